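#' @importFrom rlang .data abort warn inform
#' @importFrom dplyr %>%
NULL

# IUPAC nucleotide codes accepted in motif patterns, mapped to the set of
# sequence letters each one matches. Sequence 'N' is matched only by motif 'N'
# (an unknown base is never assumed to complete a hotspot).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  W = "W", S = "S", R = "Y", Y = "R", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Reverse complement of a DNA or IUPAC string
#'
#' @param x Character vector of uppercase DNA/IUPAC strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AGCTNT")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    letters <- strsplit(s, "", fixed = TRUE)[[1]]
    comp <- IUPAC_COMPLEMENT[letters]
    if (anyNA(comp)) {
      abort(paste0("non-IUPAC letter in sequence: ", s))
    }
    paste(rev(unname(comp)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Translate an IUPAC pattern into a plain regex (one character class per
# position). Overlapping matches are recovered with a lookahead by callers.
iupac_to_regex <- function(iupac) {
  letters <- strsplit(iupac, "", fixed = TRUE)[[1]]
  bad <- setdiff(letters, names(IUPAC_SETS))
  if (length(bad) > 0) {
    abort(paste0("motif letter outside IUPAC alphabet: ", paste(bad, collapse = ", ")))
  }
  paste(vapply(letters, function(l) {
    set <- IUPAC_SETS[[l]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Run a function with a private RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All simulator randomness flows through
# this so fixed seeds give identical outputs regardless of call order.
with_private_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

# Deterministic substream seed for unit i under master seed `seed`;
# stays below 2^31 so it is a valid R integer seed.
split_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483629)
}
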