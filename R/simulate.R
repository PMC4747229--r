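#' Synthetic PTEN-like reference coding sequence
#'
#' A 1212 nt synthetic coding sequence reproducing the repeat contexts at
#' which recurrent PTEN frameshifts arise: (A)6 homopolymers ending at c.800
#' and c.968, a (TACT)2 tetranucleotide block at c.954–961, a TT
#' dinucleotide context at c.531–532, and non-repeat control regions
#' elsewhere. Reference bases at the recurrent substitution positions (c.29,
#' c.359, c.365, c.376, c.531, c.697, c.700, c.974) match their HGVS
#' descriptions so the example PTEN case list ([pten_mutations()]) replays
#' cleanly. The background is a period-7 pattern, which contains no tandem
#' repeat of any unit of 1–6 bp, so only the planted contexts are flagged.
#' This is a synthetic stand-in for the real transcript, not its sequence.
#'
#' @return A character scalar of length-1212 coding sequence.
#' @export
pten_reference <- function() {
  len <- 1212L
  s <- strsplit(strrep("ACGTAGC", ceiling(len / 7)), "")[[1]][seq_len(len)]
  put <- function(s, at, what) {
    s[at:(at + nchar(what) - 1L)] <- strsplit(what, "")[[1]]
    s
  }
  s <- put(s, 29L, "G")                      # c.29G>T
  s <- put(s, 359L, "G")                     # c.359G>A
  s <- put(s, 365L, "T")                     # c.365T>A
  s <- put(s, 376L, "G")                     # c.376G>A
  s <- put(s, 530L, "C")                     # guard
  s <- put(s, 531L, "TT")                    # c.531_532dupTT / c.531T>G
  s <- put(s, 533L, "G")                     # guard
  s <- put(s, 697L, "C")                     # c.697C>T
  s <- put(s, 700L, "C")                     # c.700C>T
  s <- put(s, 794L, "C")                     # guard
  s <- put(s, 795L, "AAAAAA")                # (A)6 ending at c.800
  s <- put(s, 801L, "G")                     # guard
  s <- put(s, 953L, "G")                     # guard (breaks any upstream TACT)
  s <- put(s, 954L, "TACTTACT")              # (TACT)2 at c.954-961
  s <- put(s, 962L, "G")                     # guard
  s <- put(s, 963L, "AAAAAA")                # (A)6 ending at c.968
  s <- put(s, 969L, "G")                     # guard
  s <- put(s, 974L, "T")                     # c.974T>G
  paste(s, collapse = "")
}

# Generic synthetic coding sequence with planted mononucleotide runs of
# lengths 2..6 (and a (C)5), used as the slippage substrate for simulated
# genes without a dedicated fixture. Deterministic; no RNG.
synthetic_cds <- function(length = 840L) {
  s <- strsplit(strrep("ACGTAGC", ceiling(length / 7)), "")[[1]][
    seq_len(length)]
  put <- function(s, at, what) {
    s[at:(at + nchar(what) - 1L)] <- strsplit(what, "")[[1]]
    s
  }
  runs <- c(2L, 3L, 4L, 5L, 6L)
  at <- c(101L, 151L, 201L, 251L, 301L)
  for (i in seq_along(runs)) {
    s <- put(s, at[i] - 1L, "C")
    s <- put(s, at[i], strrep("A", runs[i]))
    s <- put(s, at[i] + runs[i], "G")
  }
  s <- put(s, 350L, "G")
  s <- put(s, 351L, "CCCCC")
  s <- put(s, 356L, "A")
  paste(s, collapse = "")
}

#' Reference coding-sequence fixtures
#'
#' Builds the named set of synthetic coding sequences the annotator and
#' simulator run against: the PTEN-like fixture with its reported repeat
#' contexts plus a generic repeat-bearing sequence for every other panel
#' gene. Optionally written to FASTA.
#'
#' @param genes Gene symbols to cover (default [panel_genes()]).
#' @param path Optional FASTA output path.
#' @return Named character vector of coding sequences.
#' @export
reference_fixtures <- function(genes = panel_genes(), path = NULL) {
  refs <- stats::setNames(
    vapply(genes, function(g) {
      if (g == "PTEN") pten_reference() else synthetic_cds()
    }, character(1)),
    genes
  )
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs), path)
  }
  refs
}

# Maximal mononucleotide runs of a sequence, via run-length encoding.
homopolymer_runs <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  r <- rle(chars)
  end <- cumsum(r$lengths)
  tibble::tibble(base = r$values,
                 start = end - r$lengths + 1L,
                 end = end,
                 len = r$lengths)
}

#' Parameters of the synthetic-cohort generator
#'
#' Bundles every distributional constant of the simulator. Defaults emulate
#' the reference cohort: 113 MSS and 29 MSI-H tumors; total burden 2.4 +/-
#' 1.6 (MSS) and 3.7 +/- 2.2 (MSI-H) mutations/tumor; per-gene tumor-level
#' mutation probabilities from [gene_mutation_counts()]; variant-class
#' probabilities from the per-class totals of each group (229/33/3/4 of 269
#' for MSS, 92/12/3/1 of 108 for MSI-H); a 1000-fold slippage-rate ratio
#' between runs of 6 and runs of 2; and roughly one CRC131-like MSS
#' hypermutator per 113 tumors.
#'
#' @param n_mss,n_msih Tumor counts per group.
#' @param burden Per-group `c(mean, sd)` of total mutations/tumor.
#' @param uncommon_burden Per-group `c(mean, sd)` of the burden outside the
#'   nine common genes (reference values the generated cohorts should
#'   approximate; the generator realizes them through `gene_freqs` and the
#'   background pool rather than drawing them directly).
#' @param gene_freqs Per-group named vectors of tumor-level per-gene
#'   mutation probabilities.
#' @param class_probs Per-group probabilities over [mutation_classes()].
#' @param slippage_ratio_6_vs_2 Rate multiplier for indel placement in runs
#'   of 6 versus runs of 2 (log-linearly interpolated for intermediate run
#'   lengths).
#' @param hypermutator_prob Probability that an MSS tumor is a
#'   CRC131-like hypermutation outlier.
#' @param p_stop Per-codon stop probability for simulated frameshift
#'   extents.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(
    n_mss = 113L,
    n_msih = 29L,
    burden = list(MSS = c(mean = 2.4, sd = 1.6),
                  MSI_H = c(mean = 3.7, sd = 2.2)),
    uncommon_burden = list(MSS = c(mean = 0.2, sd = 0.8),
                           MSI_H = c(mean = 1.6, sd = 1.5)),
    gene_freqs = default_gene_freqs(),
    class_probs = list(
      MSS = c(substitution = 229, deletion = 33,
              insertion_duplication = 3, splice = 4) / 269,
      MSI_H = c(substitution = 92, deletion = 12,
                insertion_duplication = 3, splice = 1) / 108),
    slippage_ratio_6_vs_2 = 1000,
    hypermutator_prob = 1 / 113,
    p_stop = 3 / 64,
    seed = 1L) {
  stopifnot(n_mss >= 1, n_msih >= 1,
            all(unlist(gene_freqs) >= 0), all(unlist(gene_freqs) <= 1),
            hypermutator_prob >= 0, hypermutator_prob <= 1,
            slippage_ratio_6_vs_2 > 0,
            p_stop > 0, p_stop <= 1,
            all(vapply(burden, function(b) b[["mean"]] >= 0 && b[["sd"]] >= 0,
                       logical(1))))
  structure(list(n_mss = as.integer(n_mss), n_msih = as.integer(n_msih),
                 burden = burden, uncommon_burden = uncommon_burden,
                 gene_freqs = gene_freqs, class_probs = class_probs,
                 slippage_ratio_6_vs_2 = slippage_ratio_6_vs_2,
                 hypermutator_prob = hypermutator_prob,
                 p_stop = p_stop, seed = as.integer(seed)),
            class = "simulation_params")
}

#' @rdname simulation_params
#' @export
default_gene_freqs <- function() {
  counts <- gene_mutation_counts()
  list(MSS = stats::setNames(counts$mss_n / 113, counts$gene),
       MSI_H = stats::setNames(counts$msih_n / 29, counts$gene))
}

# Overdispersed counts: negative binomial moment-matched from mean/SD, with
# a logged Poisson fallback when the requested variance does not exceed the
# mean (NB cannot be underdispersed).
draw_counts <- function(n, mean, sd) {
  if (mean <= 0) return(integer(n))
  v <- sd^2
  if (v > mean) {
    size <- mean^2 / (v - mean)
    stats::rnbinom(n, size = size, mu = mean)
  } else {
    message("draw_counts: sd^2 <= mean (", v, " <= ", mean,
            "); Poisson fallback")
    stats::rpois(n, mean)
  }
}

aa_letters <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Generate a synthetic cohort with truth labels
#'
#' Draws a cohort with the statistical structure the downstream analyses
#' assume. Per tumor, gene-level mutation presence is Bernoulli at the
#' group's per-gene probabilities; the remaining burden is filled from a
#' background gene pool with a count drawn so that the group's total burden
#' matches the requested mean and SD exactly in expectation (negative
#' binomial on the residual moments, Poisson fallback when underdispersed).
#' Simulated indels are placed at mononucleotide runs of the gene's
#' reference sequence with probability proportional to
#' `slippage_ratio_6_vs_2 ^ ((run_length - 2) / 4)` for MSI-H tumors
#' (uniform across runs for MSS), so slippage concentrates in long
#' homopolymers; frameshift extents are geometric with per-codon stop
#' probability `p_stop`. MSS tumors become CRC131-like hypermutators with
#' probability `hypermutator_prob`. Identical parameters and seed give an
#' identical cohort.
#'
#' @param params A [simulation_params()] object.
#' @return List with elements `cohort` (an `msi_cohort`), `truth` (tibble
#'   `tumor_id`, `true_status`, `is_hypermutator`) and `references` (the
#'   fixture sequences used).
#' @export
generate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  genes_all <- union(names(params$gene_freqs$MSS), background_pool_genes())
  refs <- reference_fixtures(genes_all)
  runs <- lapply(refs, homopolymer_runs)

  all_samples <- list()
  all_muts <- list()
  all_truth <- list()
  for (group in c("MSS", "MSI_H")) {
    n <- if (group == "MSS") params$n_mss else params$n_msih
    freqs <- params$gene_freqs[[group]]
    b <- params$burden[[group]]
    mean_bg <- b[["mean"]] - sum(freqs)
    if (mean_bg < 0) {
      warning("gene_freqs for ", group, " sum above the burden mean; ",
              "background fill disabled")
      mean_bg <- 0
    }
    var_bg <- max(0, b[["sd"]]^2 - sum(freqs * (1 - freqs)))
    bg_counts <- draw_counts(n, mean_bg, sqrt(var_bg))
    hyper <- if (group == "MSS") {
      stats::runif(n) < params$hypermutator_prob
    } else rep(FALSE, n)
    bg_counts[hyper] <- bg_counts[hyper] + 1L + stats::rpois(sum(hyper), 11)
    hit_mat <- vapply(freqs, function(p) stats::rbinom(n, 1, p) == 1,
                      logical(n))
    if (n == 1) hit_mat <- matrix(hit_mat, nrow = 1)

    ids <- sprintf("%s%03d", if (group == "MSS") "MSS" else "MSIH",
                   seq_len(n))
    prob <- covariate_probs(group)
    all_samples[[group]] <- tibble::tibble(
      tumor_id = ids, msi_status = group,
      site = sample(names(prob$site), n, TRUE, prob$site),
      stage = sample(names(prob$stage), n, TRUE, prob$stage),
      specimen = sample(names(prob$specimen), n, TRUE, prob$specimen),
      sex = sample(names(prob$sex), n, TRUE, prob$sex),
      age = sample(prob$age, n, TRUE)
    )
    all_truth[[group]] <- tibble::tibble(tumor_id = ids, true_status = group,
                                         is_hypermutator = hyper)
    for (i in seq_len(n)) {
      gene_list <- c(names(freqs)[hit_mat[i, ]],
                     sample(background_pool_genes(), bg_counts[i],
                            replace = TRUE))
      if (length(gene_list) == 0) next
      m <- vapply(gene_list, function(g) {
        simulate_mutation(g, group, params, refs[[g]], runs[[g]])
      }, character(4))
      keep <- !duplicated(paste(m[1, ], m[2, ]))
      all_muts[[length(all_muts) + 1]] <-
        list(tumor_id = rep(ids[i], sum(keep)), gene = m[1, keep],
             hgvs_c = m[2, keep], hgvs_p = m[3, keep],
             variant_class = m[4, keep])
    }
  }
  muts <- tibble::tibble(
    tumor_id = unlist(lapply(all_muts, `[[`, "tumor_id")) %||% character(),
    gene = unlist(lapply(all_muts, `[[`, "gene")) %||% character(),
    hgvs_c = unlist(lapply(all_muts, `[[`, "hgvs_c")) %||% character(),
    hgvs_p = unlist(lapply(all_muts, `[[`, "hgvs_p")) %||% character(),
    variant_class = unlist(lapply(all_muts, `[[`, "variant_class")) %||%
      character()
  )
  list(
    cohort = cohort(muts, samples = dplyr::bind_rows(all_samples),
                    name = "synthetic"),
    truth = dplyr::bind_rows(all_truth),
    references = refs
  )
}

covariate_probs <- function(group) {
  if (group == "MSS") {
    list(site = c(right = 35, left = 73, unknown = 5) / 113,
         stage = c(I_III = 53, IV = 59, unknown = 1) / 113,
         specimen = c(primary = 84, metastasis = 29) / 113,
         sex = c(female = 55, male = 58) / 113,
         age = 25:84)
  } else {
    list(site = c(right = 18, left = 10, unknown = 1) / 29,
         stage = c(I_III = 22, IV = 7) / 29,
         specimen = c(primary = 28, metastasis = 1) / 29,
         sex = c(female = 16, male = 13) / 29,
         age = 26:89)
  }
}

# One simulated mutation in `gene` for a tumor of `group`; returns
# c(gene, hgvs_c, hgvs_p, variant_class).
simulate_mutation <- function(gene, group, params, ref, ref_runs) {
  n_ref <- nchar(ref)
  cls <- sample(names(params$class_probs[[group]]), 1,
                prob = params$class_probs[[group]])
  aa <- function() sample(aa_letters(), 1)
  if (cls == "substitution") {
    pos <- sample.int(n_ref, 1)
    refb <- substr(ref, pos, pos)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    c(gene, sprintf("c.%d%s>%s", pos, refb, altb),
      sprintf("p.%s%d%s", aa(), ceiling(pos / 3), aa()), cls)
  } else if (cls == "splice") {
    pos <- sample.int(n_ref, 1)
    c(gene, sprintf("c.%d+2T>C", pos), NA_character_, cls)
  } else {
    # replication-slippage indel at a mononucleotide run; weight rises
    # log-linearly with run length for MSI-H tumors
    w <- if (group == "MSI_H") {
      params$slippage_ratio_6_vs_2^((pmin(ref_runs$len, 6) - 2) / 4)
    } else {
      rep(1, nrow(ref_runs))
    }
    r <- ref_runs[sample.int(nrow(ref_runs), 1, prob = w), ]
    fs <- stats::rgeom(1, params$p_stop) + 1L
    hgvs_p <- sprintf("p.%s%d%sfs*%d", aa(), ceiling(r$end / 3), aa(), fs)
    op <- if (cls == "deletion") "del" else "dup"
    c(gene, sprintf("c.%d%s%s", r$end, op, r$base), hgvs_p, cls)
  }
}

#' Simulate the PCR microsatellite assay
#'
#' Draws independent per-locus stable/unstable calls at the five
#' mononucleotide loci (Bernoulli at the per-status instability
#' probability) plus the two pentanucleotide control loci, and applies the
#' ">= 2 unstable mononucleotide loci" call rule via [msi_assay_call()].
#' The default per-locus instability probabilities are placeholders — no
#' published per-locus rates back them — and should be set from assay
#' validation data when available.
#'
#' @param truth Tibble with columns `tumor_id`, `true_status` (e.g. from
#'   [generate_cohort()]).
#' @param instability_probs Named list of per-locus instability
#'   probabilities by true status.
#' @param penta_prob Instability probability of the pentanucleotide control
#'   loci.
#' @param seed Integer seed.
#' @return Tibble with one row per tumor: `tumor_id`, one column per locus,
#'   `n_unstable_mono`, `call`.
#' @export
simulate_msi_assay <- function(truth,
                               instability_probs = list(MSS = 0.02,
                                                        MSI_H = 0.90),
                               penta_prob = 0.01,
                               seed = 1L) {
  stopifnot(all(unlist(instability_probs) >= 0),
            all(unlist(instability_probs) <= 1),
            penta_prob >= 0, penta_prob <= 1)
  set.seed(seed)
  loci <- c(msi_mono_loci(), msi_penta_loci())
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    p <- instability_probs[[truth$true_status[i]]]
    calls <- c(
      ifelse(stats::runif(length(msi_mono_loci())) < p, "unstable", "stable"),
      ifelse(stats::runif(length(msi_penta_loci())) < penta_prob,
             "unstable", "stable")
    )
    names(calls) <- loci
    res <- msi_assay_call(calls)
    out <- tibble::as_tibble(as.list(calls))
    out$tumor_id <- truth$tumor_id[i]
    out$n_unstable_mono <- res$n_unstable_mono
    out$call <- res$call
    out
  })
  out <- dplyr::bind_rows(rows)
  out[, c("tumor_id", loci, "n_unstable_mono", "call")]
}
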