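#' Genotype models for the synthetic mutation landscape
#'
#' Each genotype is summarised by three quantities: the fraction of AID
#' deamination events that escape faithful repair (`escape_fraction`), the
#' substitution spectrum at the deaminated cytosine (weights over C>T, C>G,
#' C>A; G sites are mirrored), and a multiplier for collateral A/T-site
#' mutations per escaped deamination (`at_rate_scale`, the repair-patch
#' footprint of mismatch repair).
#'
#' Presets encode the repair biology qualitatively: the AID-null control
#' (`Aicda_KO`) has zero effective deamination; the double repair knockout
#' (`UngMsh2_DKO`, *Ung-/-Msh2-/-*) leaves every uracil in place so all
#' escaped events replicate into pure C>T/G>A transitions with no A/T
#' phase; the single knockouts (`Ung_KO` = *Ung-/-Msh2+/-*, `Msh2_KO` =
#' *Ung+/-Msh2-/-*) and the double heterozygote (`DoubleHet` =
#' *Ung+/-Msh2+/-*) retain one or both backup pathways and show small,
#' mutually similar escape fractions.
#'
#' @param name One of `"Aicda_KO"`, `"UngMsh2_DKO"`, `"Ung_KO"`,
#'   `"Msh2_KO"`, `"DoubleHet"`.
#' @param escape_fraction,spectrum,at_rate_scale Optional overrides of the
#'   preset values. `spectrum` is a length-3 numeric (C>T, C>G, C>A weights)
#'   summing to 1.
#' @return An object of class `genotype_model`.
#' @examples
#' genotype_model("UngMsh2_DKO")
#' @export
genotype_model <- function(name,
                           escape_fraction = NULL,
                           spectrum = NULL,
                           at_rate_scale = NULL) {
  presets <- list(
    Aicda_KO = list(escape_fraction = 0, spectrum = c(1, 0, 0),
                    at_rate_scale = 0),
    UngMsh2_DKO = list(escape_fraction = 1, spectrum = c(1, 0, 0),
                       at_rate_scale = 0),
    Ung_KO = list(escape_fraction = 0.10, spectrum = c(0.90, 0.05, 0.05),
                  at_rate_scale = 0.30),
    Msh2_KO = list(escape_fraction = 0.10, spectrum = c(0.50, 0.30, 0.20),
                   at_rate_scale = 0.05),
    DoubleHet = list(escape_fraction = 0.04, spectrum = c(0.70, 0.20, 0.10),
                     at_rate_scale = 0.20)
  )
  if (!name %in% names(presets)) {
    abort(paste0("unknown genotype: ", name, " (expected one of ",
                 paste(names(presets), collapse = ", "), ")"))
  }
  g <- presets[[name]]
  if (!is.null(escape_fraction)) g$escape_fraction <- escape_fraction
  if (!is.null(spectrum)) g$spectrum <- spectrum
  if (!is.null(at_rate_scale)) g$at_rate_scale <- at_rate_scale
  stopifnot(g$escape_fraction >= 0, g$escape_fraction <= 1,
            length(g$spectrum) == 3, all(g$spectrum >= 0),
            abs(sum(g$spectrum) - 1) < 1e-9, g$at_rate_scale >= 0)
  if (name == "Aicda_KO" && g$escape_fraction != 0) {
    abort("Aicda_KO must have zero effective deamination")
  }
  structure(c(list(name = name), g), class = "genotype_model")
}

#' Simulation configuration
#'
#' Defaults describe a targeted-capture experiment over TSS-anchored 500-bp
#' windows: 200 regions at 50% GC, mean coverage 500x, per-base sequencing
#' substitution error 1e-4, heterozygous germline SNPs at 1e-3 per bp, base
#' deamination (expected mutant-allele fraction at a non-hotspot C before
#' repair) 2e-4, and hotspot multipliers WRCY x10 and AGCTNT x25 so the
#' motif-mutability ordering AGCTNT > WRCY > background is planted.
#'
#' @param n_regions,region_length,gc_content,base_deamination Region panel
#'   and deamination intensity.
#' @param motif_multipliers Named numeric; names must be preset motif names.
#' @param depth_mean,error_rate,snp_rate Sequencing model.
#' @param hotspot_only If TRUE, deamination is restricted to the motifs in
#'   `motif_multipliers`: cytosines outside every listed hotspot receive
#'   zero deamination instead of the base rate.
#' @param seed Master seed; all randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_regions = 200,
                              region_length = 500,
                              gc_content = 0.5,
                              base_deamination = 2e-4,
                              motif_multipliers = c(WRCY = 10, AGCTNT = 25),
                              depth_mean = 500,
                              error_rate = 1e-4,
                              snp_rate = 1e-3,
                              hotspot_only = FALSE,
                              seed = 1) {
  stopifnot(n_regions >= 1, region_length >= 1,
            gc_content > 0, gc_content <= 1,
            base_deamination >= 0, base_deamination <= 1,
            depth_mean > 0, error_rate >= 0, error_rate <= 1,
            snp_rate >= 0, snp_rate <= 1)
  structure(list(
    n_regions = as.integer(n_regions),
    region_length = as.integer(region_length),
    gc_content = gc_content,
    base_deamination = base_deamination,
    motif_multipliers = motif_multipliers,
    depth_mean = depth_mean,
    error_rate = error_rate,
    snp_rate = snp_rate,
    hotspot_only = isTRUE(hotspot_only),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate capture regions and a germline SNP mask
#'
#' Generates random region sequences at the configured GC content and draws
#' heterozygous SNP positions at `snp_rate` per bp (allele fraction 0.5,
#' random alternate base). Each region uses its own seed substream so output
#' is deterministic under the master seed.
#'
#' @param config A [simulation_config()].
#' @return List with `regions` (tibble as from [load_regions()]) and `snps`
#'   (tibble `region_id`, `pos`, `alt`).
#' @export
simulate_regions <- function(config) {
  gc <- config$gc_content
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  res <- purrr::map(seq_len(config$n_regions), function(i) {
    with_private_seed(split_seed(config$seed, i), {
      bases <- sample(names(base_probs), config$region_length,
                      replace = TRUE, prob = base_probs)
      snp_at <- which(stats::runif(config$region_length) < config$snp_rate)
      alt <- vapply(snp_at, function(p) {
        sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1)
      }, character(1))
      list(sequence = paste(bases, collapse = ""), snp_pos = snp_at - 1L,
           snp_alt = alt)
    })
  })
  ids <- sprintf("r%04d", seq_len(config$n_regions))
  regions <- tibble::tibble(
    region_id = ids,
    gene = ids,
    chrom = "chrSim",
    start = (seq_len(config$n_regions) - 1L) * (config$region_length + 100L),
    end = (seq_len(config$n_regions) - 1L) * (config$region_length + 100L) +
      config$region_length,
    sequence = vapply(res, `[[`, character(1), "sequence")
  )
  snps <- purrr::map_dfr(seq_along(res), function(i) {
    tibble::tibble(region_id = ids[i],
                   pos = res[[i]]$snp_pos,
                   alt = res[[i]]$snp_alt)
  })
  list(regions = regions, snps = snps)
}

#' Expected per-site mutant-allele fractions for a genotype
#'
#' The simulation ground truth. At each cytosine (plus frame) or guanine
#' (minus frame) the deamination fraction is `base_deamination` times the
#' largest motif multiplier among the hotspot instances covering the site in
#' the matching frame (1 if none). Per-substitution expected fractions are
#' deamination x escape_fraction x spectrum weight (G sites mirrored).
#' Collateral A/T mutations are spread uniformly over the region's A/T
#' sites, scaled by `at_rate_scale` per escaped deamination.
#'
#' @param regions Regions tibble.
#' @param genotype A [genotype_model()].
#' @param config A [simulation_config()] (supplies `base_deamination` and
#'   `motif_multipliers`).
#' @param hotspots Hotspot annotation from [annotate_hotspots()] computed on
#'   `regions` for the motifs named in `config$motif_multipliers`.
#' @param target_ids Region ids carrying AID activity; regions not listed
#'   get an all-zero truth (default: all regions are targets).
#' @return Tibble `region_id`, `pos`, `ref`, `to_A`, `to_C`, `to_G`, `to_T`
#'   of expected mutant-allele fractions.
#' @export
expected_site_frequencies <- function(regions, genotype, config, hotspots,
                                      target_ids = regions$region_id) {
  stopifnot(inherits(genotype, "genotype_model"))
  mult <- config$motif_multipliers
  lens <- nchar(regions$sequence)
  ref <- unlist(strsplit(regions$sequence, "", fixed = TRUE),
                use.names = FALSE)
  rid <- rep(regions$region_id, lens)
  pos <- unlist(lapply(lens, function(n) seq_len(n) - 1L), use.names = FALSE)
  n <- length(ref)
  out <- matrix(0, nrow = n, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  active <- rid %in% target_ids
  if (any(active) && genotype$escape_fraction > 0 &&
      config$base_deamination > 0) {
    key <- paste(rid, pos)
    # under hotspot-only restriction, off-motif cytosines get no deamination
    site_mult <- rep(if (isTRUE(config$hotspot_only)) 0 else 1, n)
    if (nrow(hotspots) > 0) {
      hs <- hotspots
      hs$mult <- unname(mult[hs$motif_name])
      hs$mult[is.na(hs$mult)] <- 1
      idx <- match(paste(hs$region_id, hs$position), key)
      ok <- !is.na(idx) &
        ((hs$strand == "+" & ref[idx] == "C") |
           (hs$strand == "-" & ref[idx] == "G"))
      if (any(ok)) {
        mx <- tapply(hs$mult[ok], idx[ok], max)
        at <- as.integer(names(mx))
        site_mult[at] <- pmax(site_mult[at], mx)
      }
    }
    esc <- config$base_deamination * site_mult *
      genotype$escape_fraction * active
    w <- genotype$spectrum
    is_c <- ref == "C"
    is_g <- ref == "G"
    out[is_c, "T"] <- esc[is_c] * w[1]
    out[is_c, "G"] <- esc[is_c] * w[2]
    out[is_c, "A"] <- esc[is_c] * w[3]
    out[is_g, "A"] <- esc[is_g] * w[1]
    out[is_g, "C"] <- esc[is_g] * w[2]
    out[is_g, "T"] <- esc[is_g] * w[3]
    if (genotype$at_rate_scale > 0) {
      # collateral A/T load is spread uniformly within each region
      is_at <- ref == "A" | ref == "T"
      esc_tot <- tapply(esc[is_c | is_g], rid[is_c | is_g], sum)
      n_at <- tapply(is_at, rid, sum)
      per_site <- genotype$at_rate_scale *
        as.numeric(esc_tot[rid]) / pmax(as.numeric(n_at[rid]), 1)
      per_site[is.na(per_site)] <- 0
      for (b in c("A", "C", "G", "T")) {
        rows <- is_at & ref != b
        out[rows, b] <- out[rows, b] + per_site[rows] / 3
      }
    }
  }
  tibble::tibble(region_id = rid, pos = pos, ref = ref,
                 to_A = out[, "A"], to_C = out[, "C"],
                 to_G = out[, "G"], to_T = out[, "T"])
}

#' Simulate a per-base count table from a site truth
#'
#' Per position, depth is Poisson(`depth_mean`) and base calls are
#' multinomial with alternate-base probabilities equal to the truth
#' fractions plus `error_rate`/3 per non-reference base, plus 0.5 toward the
#' alternate allele at heterozygous SNP positions; the reference base takes
#' the remaining mass.
#'
#' @param truth Tibble from [expected_site_frequencies()].
#' @param snps SNP tibble (`region_id`, `pos`, `alt`) or NULL.
#' @param depth_mean,error_rate Sequencing model.
#' @param seed Seed for this draw.
#' @return Site-count tibble (`region_id`, `pos`, `ref`, `depth`, `A`, `C`,
#'   `G`, `T`).
#' @export
simulate_counts <- function(truth, snps, depth_mean, error_rate, seed) {
  bases <- c("A", "C", "G", "T")
  prob <- as.matrix(truth[, c("to_A", "to_C", "to_G", "to_T")])
  colnames(prob) <- bases
  for (b in bases) {
    prob[truth$ref != b, b] <- prob[truth$ref != b, b] + error_rate / 3
    prob[truth$ref == b, b] <- 0
  }
  if (!is.null(snps) && nrow(snps) > 0) {
    key <- paste(truth$region_id, truth$pos)
    skey <- paste(snps$region_id, snps$pos)
    idx <- match(skey, key)
    keep <- !is.na(idx)
    if (any(keep)) {
      prob[cbind(idx[keep], match(snps$alt[keep], bases))] <-
        prob[cbind(idx[keep], match(snps$alt[keep], bases))] + 0.5
    }
  }
  if (any(rowSums(prob) > 1)) abort("alternate-base probabilities exceed 1")
  # sequential conditional binomials over the alt bases; the reference base
  # absorbs the remaining probability mass and the remaining depth
  with_private_seed(seed, {
    depth <- stats::rpois(nrow(truth), depth_mean)
    out <- matrix(0L, nrow(truth), 4, dimnames = list(NULL, bases))
    remaining <- depth
    rem_p <- rep(1, nrow(truth))
    for (b in bases) {
      pj <- ifelse(rem_p > 0, pmin(prob[, b] / rem_p, 1), 0)
      nb <- stats::rbinom(nrow(truth), remaining, pj)
      out[, b] <- nb
      remaining <- remaining - nb
      rem_p <- rem_p - prob[, b]
    }
    ref_idx <- match(truth$ref, bases)
    out[cbind(seq_len(nrow(truth)), ref_idx)] <- remaining
    tibble::tibble(region_id = truth$region_id, pos = truth$pos,
                   ref = truth$ref, depth = depth,
                   A = out[, "A"], C = out[, "C"],
                   G = out[, "G"], T = out[, "T"])
  })
}

#' Simulate a gene-level feature table with a planted PolII/Spt5 interaction
#'
#' Continuous features (expression, transcription rate, PolII and Spt5
#' densities) are lognormal around a shared latent transcriptional activity;
#' binary chromatin marks are Bernoulli with activity-linked probabilities.
#' The target label is Bernoulli with
#' `P(target) = plogis(baseline_logit + interaction_logit * high)` where
#' `high` indicates PolII and Spt5 both above their `quantile_threshold`
#' quantile — the combination reported to predict AID specificity.
#'
#' @param n_genes Number of genes (>= 50).
#' @param effect List with `baseline_logit`, `interaction_logit`,
#'   `quantile_threshold`.
#' @param seed Seed.
#' @return Tibble with [prepare_features()]-compatible columns plus `label`
#'   (factor target/nontarget) and `high_polII_spt5` (the true stratum).
#' @export
simulate_feature_table <- function(n_genes,
                                   effect = list(baseline_logit = -3,
                                                 interaction_logit = 4.2,
                                                 quantile_threshold = 0.75),
                                   seed = 1) {
  stopifnot(n_genes >= 50)
  with_private_seed(seed, {
    z <- stats::rnorm(n_genes)
    expression_tpm <- exp(1.0 + 0.8 * z + stats::rnorm(n_genes, 0, 0.6))
    transcription_rate <- exp(0.5 + 0.7 * z + stats::rnorm(n_genes, 0, 0.6))
    polII_density <- exp(0.7 * z + stats::rnorm(n_genes, 0, 0.7))
    spt5_density <- exp(0.7 * z + stats::rnorm(n_genes, 0, 0.7))
    bin <- function(shift) stats::rbinom(n_genes, 1, stats::plogis(z + shift))
    med12 <- bin(-1)
    h3k4me1 <- bin(0)
    h3k36me3 <- bin(-0.5)
    h3k79me2 <- bin(-0.5)
    superenhancer <- bin(-2)
    convt <- bin(-1.5)
    q <- effect$quantile_threshold
    high <- polII_density > stats::quantile(polII_density, q) &
      spt5_density > stats::quantile(spt5_density, q)
    p_target <- stats::plogis(effect$baseline_logit +
                                effect$interaction_logit * as.numeric(high))
    label <- factor(ifelse(stats::rbinom(n_genes, 1, p_target) == 1,
                           "target", "nontarget"),
                    levels = c("nontarget", "target"))
    background_freq <- stats::rgamma(n_genes, shape = 2, scale = 5e-5)
    tibble::tibble(
      gene = sprintf("g%05d", seq_len(n_genes)),
      expression_tpm = expression_tpm,
      transcription_rate = transcription_rate,
      polII_density = polII_density,
      spt5_density = spt5_density,
      med12 = med12, h3k4me1 = h3k4me1, h3k36me3 = h3k36me3,
      h3k79me2 = h3k79me2, superenhancer = superenhancer, convt = convt,
      background_freq = background_freq,
      high_polII_spt5 = high,
      label = label
    )
  })
}

#' Simulate a full targeted-capture experiment
#'
#' Convenience wrapper: regions + SNP mask, hotspot annotation for the
#' configured motifs, a target subset of regions, genotype truths (the
#' AID-null control always has an all-zero truth) and per-genotype count
#' tables, each genotype drawn from its own seed substream.
#'
#' @param config A [simulation_config()].
#' @param genotypes Character vector of genotype names (see
#'   [genotype_model()]).
#' @param target_fraction Fraction of regions planted as AID targets
#'   (sampled; 0 gives a null experiment).
#' @return List with `regions`, `snps`, `hotspots`, `target_ids`, `truth`
#'   (named list per genotype) and `counts` (named list per genotype).
#' @export
simulate_shm_experiment <- function(config,
                                    genotypes = c("UngMsh2_DKO", "Aicda_KO"),
                                    target_fraction = 0.05) {
  sim <- simulate_regions(config)
  motifs <- preset_motifs(names(config$motif_multipliers))
  hotspots <- annotate_hotspots(sim$regions, motifs)
  n_targets <- round(target_fraction * nrow(sim$regions))
  target_ids <- if (n_targets > 0) {
    with_private_seed(split_seed(config$seed, 999983L),
                      sample(sim$regions$region_id, n_targets))
  } else {
    character(0)
  }
  truth <- counts <- list()
  for (k in seq_along(genotypes)) {
    g <- genotype_model(genotypes[k])
    truth[[genotypes[k]]] <- expected_site_frequencies(
      sim$regions, g, config, hotspots, target_ids = target_ids)
    counts[[genotypes[k]]] <- simulate_counts(
      truth[[genotypes[k]]], sim$snps,
      depth_mean = config$depth_mean, error_rate = config$error_rate,
      seed = split_seed(config$seed, 1000003L + k))
  }
  list(regions = sim$regions, snps = sim$snps, hotspots = hotspots,
       target_ids = target_ids, truth = truth, counts = counts)
}

#' Write a simulated experiment to disk
#'
#' Emits `regions.fasta`, `regions.bed`, `snps.bed`, one
#' `counts_<genotype>.tsv` per genotype, `truth.tsv` and (if present)
#' `features.tsv` into `outdir`.
#'
#' @param sim Output of [simulate_shm_experiment()].
#' @param outdir Output directory (created if needed).
#' @param features Optional feature table from [simulate_feature_table()].
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir, features = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  # assemble the single simulated contig with gap padding
  total_len <- max(sim$regions$end)
  contig <- strrep("N", total_len)
  for (i in seq_len(nrow(sim$regions))) {
    substr(contig, sim$regions$start[i] + 1, sim$regions$end[i]) <-
      sim$regions$sequence[i]
  }
  writeLines(c(">chrSim", contig), file.path(outdir, "regions.fasta"))
  readr::write_tsv(
    dplyr::transmute(sim$regions, .data$chrom, .data$start, .data$end,
                     .data$region_id),
    file.path(outdir, "regions.bed"), col_names = FALSE)
  snp_bed <- dplyr::inner_join(sim$snps,
                               dplyr::select(sim$regions, "region_id",
                                             "chrom", "start"),
                               by = "region_id")
  readr::write_tsv(
    tibble::tibble(chrom = snp_bed$chrom,
                   start = snp_bed$start + snp_bed$pos,
                   end = snp_bed$start + snp_bed$pos + 1L,
                   name = paste0("snp_", snp_bed$alt)),
    file.path(outdir, "snps.bed"), col_names = FALSE)
  for (g in names(sim$counts)) {
    write_counts_tsv(sim$counts[[g]],
                     file.path(outdir, paste0("counts_", g, ".tsv")))
  }
  readr::write_tsv(dplyr::bind_rows(sim$truth, .id = "genotype"),
                   file.path(outdir, "truth.tsv"))
  if (!is.null(features)) {
    readr::write_tsv(features, file.path(outdir, "features.tsv"))
  }
  invisible(outdir)
}
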