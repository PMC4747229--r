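#' Per-tumor mutation burden with gene-set exclusion
#'
#' Counts, for every tumor in the cohort (zero-mutation tumors included),
#' the mutations whose gene is outside `excluded_genes` and whose class is in
#' `classes`. With no exclusion and all four classes this is the total
#' burden; excluding the nine genes most commonly mutated in colorectal
#' cancer gives the "uncommon" burden that separates MSI-H tumors most
#' sharply.
#'
#' @param x An `msi_cohort`.
#' @param excluded_genes Character vector of gene symbols to drop.
#' @param classes Variant classes to count (default all of
#'   [mutation_classes()]).
#' @return Tibble with columns `tumor_id`, `burden`, one row per tumor in
#'   cohort order.
#' @export
tumor_burden <- function(x, excluded_genes = character(),
                         classes = mutation_classes()) {
  stopifnot(inherits(x, "msi_cohort"))
  muts <- x$mutations
  keep <- !(muts$gene %in% excluded_genes) & muts$variant_class %in% classes
  counts <- table(factor(muts$tumor_id[keep], levels = x$samples$tumor_id))
  tibble::tibble(tumor_id = x$samples$tumor_id,
                 burden = as.integer(counts))
}

#' Per-group burden summary (mean, SD, class totals)
#'
#' Summarizes mutation burden per MSI group: tumor count, per-class mutation
#' totals, per-tumor counts, and the mean and standard deviation of
#' mutations per tumor. The SD is the sample (n - 1) standard deviation by
#' default; set `sd_type = "population"` for the n denominator. Display
#' columns round to one decimal, mirroring how such burdens are reported;
#' full precision is retained in `mean` and `sd`.
#'
#' @param x An `msi_cohort` in which every tumor has known MSI status.
#' @param excluded_genes Genes excluded from the burden (default none).
#' @param classes Variant classes counted.
#' @param sd_type `"sample"` (n - 1) or `"population"` (n).
#' @return Tibble with one row per group (`MSS`, `MSI_H`): `group`,
#'   `n_tumors`, `n_substitution`, `n_deletion`, `n_insertion_duplication`,
#'   `n_splice`, `mean`, `sd`, `mean_display`, `sd_display`, and
#'   `per_tumor_counts` (list column).
#' @export
cohort_burden <- function(x, excluded_genes = character(),
                          classes = mutation_classes(),
                          sd_type = c("sample", "population")) {
  stopifnot(inherits(x, "msi_cohort"))
  sd_type <- match.arg(sd_type)
  if (any(x$samples$msi_status == "unknown")) {
    stop("evaluation error: tumors with unknown MSI status: ",
         paste(utils::head(
           x$samples$tumor_id[x$samples$msi_status == "unknown"], 5),
           collapse = ", "), call. = FALSE)
  }
  burdens <- tumor_burden(x, excluded_genes, classes)
  burdens$group <- x$samples$msi_status
  muts <- x$mutations
  keep <- !(muts$gene %in% excluded_genes) & muts$variant_class %in% classes
  muts <- muts[keep, , drop = FALSE]
  muts$group <- x$samples$msi_status[match(muts$tumor_id, x$samples$tumor_id)]

  rows <- lapply(c("MSS", "MSI_H"), function(g) {
    counts <- burdens$burden[burdens$group == g]
    if (length(counts) == 0) {
      stop("evaluation error: group ", g, " has no tumors", call. = FALSE)
    }
    cls <- table(factor(muts$variant_class[muts$group == g],
                        levels = mutation_classes()))
    m <- mean(counts)
    s <- if (length(counts) > 1) {
      if (sd_type == "sample") stats::sd(counts)
      else sqrt(mean((counts - m)^2))
    } else 0
    tibble::tibble(
      group = g, n_tumors = length(counts),
      n_substitution = as.integer(cls[["substitution"]]),
      n_deletion = as.integer(cls[["deletion"]]),
      n_insertion_duplication = as.integer(cls[["insertion_duplication"]]),
      n_splice = as.integer(cls[["splice"]]),
      mean = m, sd = s,
      mean_display = round(m, 1), sd_display = round(s, 1),
      per_tumor_counts = list(as.integer(counts))
    )
  })
  dplyr::bind_rows(rows)
}

#' Mean-plus-k-SD outlier threshold
#'
#' The burden above which a tumor is flagged as a hypermutation outlier:
#' `mean + k * sd`. At the conventional `k = 3`, a cohort with mean 2.4 and
#' SD 1.6 mutations/tumor yields 7.2.
#'
#' @param mean Group mean burden (mutations/tumor).
#' @param sd Group standard deviation (must be non-negative).
#' @param k SD multiplier (default 3).
#' @return `mean + k * sd`.
#' @examples
#' outlier_threshold(2.4, 1.6)   # 7.2
#' outlier_threshold(3.7, 2.2)   # 10.3
#' @export
outlier_threshold <- function(mean, sd, k = 3) {
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  mean + k * sd
}

#' Specify an MSI-H prediction rule
#'
#' Three rule families flag a tumor as predicted MSI-H from its mutation
#' profile: `TOTAL_GE_K` (total burden at least K), `UNCOMMON_GE_K` (burden
#' outside the excluded common-gene set at least K; default exclusion is the
#' nine common colorectal genes) and `HP_INDEL_GE_K` (at least K indel
#' mutations in homopolymer / short-tandem-repeat regions; "more than 1"
#' corresponds to K = 2).
#'
#' @param name Rule family.
#' @param k Threshold count, at least 1.
#' @param excluded_genes Exclusion set; only meaningful (and only allowed
#'   non-empty) for `UNCOMMON_GE_K`.
#' @return A `rule_spec` list.
#' @export
rule_spec <- function(name = c("TOTAL_GE_K", "UNCOMMON_GE_K", "HP_INDEL_GE_K"),
                      k,
                      excluded_genes = NULL) {
  name <- match.arg(name)
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("rule threshold k must be >= 1", call. = FALSE)
  if (is.null(excluded_genes)) {
    excluded_genes <- if (name == "UNCOMMON_GE_K") common_crc_genes()
                      else character(0)
  }
  if (name != "UNCOMMON_GE_K" && length(excluded_genes) > 0) {
    stop("excluded_genes only applies to UNCOMMON_GE_K", call. = FALSE)
  }
  structure(list(name = name, k = k, excluded_genes = excluded_genes),
            class = "rule_spec")
}

#' Per-tumor mutation profile for rule evaluation
#'
#' Computes, per tumor, the three counts the prediction rules consume: total
#' burden, burden outside the excluded common genes, and indel mutations in
#' repeat regions. The repeat-indel count requires annotations from
#' [annotate_cohort_repeats()]; without them it is `NA` and `HP_INDEL_GE_K`
#' rules cannot be evaluated.
#'
#' @param x An `msi_cohort`.
#' @param annotations Optional annotated mutation table from
#'   [annotate_cohort_repeats()].
#' @param excluded_genes Exclusion set for the `uncommon` count.
#' @return Tibble with columns `tumor_id`, `truth` (MSI status), `total`,
#'   `uncommon`, `hp_indels`.
#' @export
tumor_profiles <- function(x, annotations = NULL,
                           excluded_genes = common_crc_genes()) {
  stopifnot(inherits(x, "msi_cohort"))
  total <- tumor_burden(x)
  uncommon <- tumor_burden(x, excluded_genes = excluded_genes)
  hp <- rep(NA_integer_, nrow(x$samples))
  if (!is.null(annotations)) {
    flagged <- annotations[isTRUE_vec(annotations$in_repeat) &
                             annotations$variant_class %in%
                             c("deletion", "insertion_duplication"), ,
                           drop = FALSE]
    hp <- as.integer(table(factor(flagged$tumor_id,
                                  levels = x$samples$tumor_id)))
  }
  tibble::tibble(tumor_id = x$samples$tumor_id,
                 truth = x$samples$msi_status,
                 total = total$burden,
                 uncommon = uncommon$burden,
                 hp_indels = hp)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Apply an MSI-H prediction rule to tumor profiles
#'
#' @param profiles Tibble from [tumor_profiles()] (columns `total`,
#'   `uncommon`, `hp_indels`), or any data frame with those columns.
#' @param rule A [rule_spec()].
#' @return Logical vector: `TRUE` where the rule predicts MSI-H.
#' @export
predict_msi <- function(profiles, rule) {
  stopifnot(inherits(rule, "rule_spec"))
  count <- switch(rule$name,
                  TOTAL_GE_K = profiles$total,
                  UNCOMMON_GE_K = profiles$uncommon,
                  HP_INDEL_GE_K = profiles$hp_indels)
  if (any(is.na(count))) {
    stop("evaluation error: profile counts needed by ", rule$name,
         " are missing", call. = FALSE)
  }
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  count >= rule$k
}

#' Confusion-matrix evaluation of a prediction rule
#'
#' Evaluates a rule against the MSI assay truth labels: true/false
#' positives/negatives, sensitivity `tp / (tp + fn)` and specificity
#' `tn / (tn + fp)`. Display columns round to two decimals, the precision at
#' which such operating points are conventionally reported; full precision is
#' retained in `sensitivity`/`specificity`.
#'
#' @param profiles Tibble from [tumor_profiles()] with a `truth` column in
#'   which every tumor is `"MSS"` or `"MSI_H"` and both groups are present.
#' @param rule A [rule_spec()].
#' @return One-row tibble: `rule`, `k`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `sensitivity_display`,
#'   `specificity_display`.
#' @export
evaluate_rule <- function(profiles, rule) {
  truth <- profiles$truth
  if (!all(truth %in% c("MSS", "MSI_H"))) {
    stop("evaluation error: all tumors must be labeled MSS or MSI_H",
         call. = FALSE)
  }
  if (!all(c("MSS", "MSI_H") %in% truth)) {
    stop("evaluation error: both groups must be present", call. = FALSE)
  }
  pred <- predict_msi(profiles, rule)
  tp <- sum(pred & truth == "MSI_H")
  fn <- sum(!pred & truth == "MSI_H")
  fp <- sum(pred & truth == "MSS")
  tn <- sum(!pred & truth == "MSS")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  rule_name <- rule$name
  rule_k <- rule$k
  tibble::tibble(rule = rule_name, k = rule_k,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 sensitivity_display = round(sens, 2),
                 specificity_display = round(spec, 2))
}

#' MSI assay call from per-locus stability
#'
#' Implements the PCR panel call rule: a tumor is MSI-high when novel allele
#' lengths (instability) appear at 2 or more of the five mononucleotide
#' microsatellite loci. The two pentanucleotide loci are specimen-identity
#' controls — recorded, never counted.
#'
#' @param locus_calls Named character vector of `"stable"`/`"unstable"`
#'   calls; names must include all of [msi_mono_loci()], and may include
#'   [msi_penta_loci()].
#' @return List with `locus_calls`, `n_unstable_mono` and `call` (`"MSS"` or
#'   `"MSI_H"`).
#' @examples
#' calls <- c("BAT-25" = "unstable", "BAT-26" = "stable",
#'            "NR-21" = "unstable", "NR-24" = "stable",
#'            "MONO-27" = "stable")
#' msi_assay_call(calls)$call
#' @export
msi_assay_call <- function(locus_calls) {
  locus_calls <- unlist(locus_calls)
  missing_loci <- setdiff(msi_mono_loci(), names(locus_calls))
  if (length(missing_loci) > 0) {
    stop("input error: missing mononucleotide locus/loci: ",
         paste(missing_loci, collapse = ", "), call. = FALSE)
  }
  bad <- !(locus_calls %in% c("stable", "unstable"))
  if (any(bad)) {
    stop("input error: locus calls must be 'stable' or 'unstable'",
         call. = FALSE)
  }
  n_unstable <- sum(locus_calls[msi_mono_loci()] == "unstable")
  list(locus_calls = locus_calls,
       n_unstable_mono = as.integer(n_unstable),
       call = if (n_unstable >= 2) "MSI_H" else "MSS")
}
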