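#' Pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: either input
#' paths (mutation TSV and optional samples table / FASTA of reference
#' coding sequences, or a minimal annotated VCF) or `simulate = TRUE` with
#' simulation parameters — one of the two must be present. Rule thresholds,
#' gene sets and statistics options ride along.
#'
#' @param input_maf Path to a MAF-like mutation TSV.
#' @param samples Path to a samples side-table TSV.
#' @param input_vcf Path to a minimal annotated VCF (alternative to
#'   `input_maf`).
#' @param fasta Path to reference coding sequences in FASTA; when `NULL`
#'   the bundled synthetic fixtures ([reference_fixtures()]) are used.
#' @param simulate Generate the cohort instead of reading one.
#' @param params [simulation_params()] for `simulate = TRUE`.
#' @param rules List of [rule_spec()]s to evaluate.
#' @param gene_sets Named gene sets for the frequency table.
#' @param chi_correct Yates correction for chi-square tests.
#' @param max_bin Largest explicit histogram bin (larger counts pool into an
#'   overflow bin).
#' @param out_dir Output directory for the report bundle.
#' @param seed Seed applied to simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_maf = NULL, samples = NULL,
                            input_vcf = NULL, fasta = NULL,
                            simulate = FALSE,
                            params = simulation_params(),
                            rules = default_rules(),
                            gene_sets = default_gene_sets(),
                            chi_correct = FALSE,
                            max_bin = 15L,
                            out_dir = NULL,
                            seed = NULL) {
  if (is.null(input_maf) && is.null(input_vcf) && !isTRUE(simulate)) {
    stop("pipeline_config: provide input paths or simulate = TRUE",
         call. = FALSE)
  }
  if (!is.null(seed)) params$seed <- as.integer(seed)
  structure(list(input_maf = input_maf, samples = samples,
                 input_vcf = input_vcf, fasta = fasta,
                 simulate = isTRUE(simulate), params = params,
                 rules = rules, gene_sets = gene_sets,
                 chi_correct = isTRUE(chi_correct),
                 max_bin = as.integer(max_bin),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_rules <- function() {
  list(rule_spec("TOTAL_GE_K", 6),
       rule_spec("UNCOMMON_GE_K", 2),
       rule_spec("HP_INDEL_GE_K", 2))
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; `rules` is a
#' list of `{name, k}` entries and `params` a mapping of
#' [simulation_params()] scalar fields (`n_mss`, `n_msih`,
#' `slippage_ratio_6_vs_2`, `hypermutator_prob`, `p_stop`, `seed`).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- do.call(simulation_params, y$params %||% list())
  rules <- if (is.null(y$rules)) default_rules() else
    lapply(y$rules, function(r) rule_spec(r$name, r$k))
  pipeline_config(input_maf = y$input_maf, samples = y$samples,
                  input_vcf = y$input_vcf, fasta = y$fasta,
                  simulate = isTRUE(y$simulate), params = params,
                  rules = rules,
                  chi_correct = isTRUE(y$chi_correct),
                  max_bin = y$max_bin %||% 15L,
                  out_dir = y$out_dir, seed = y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Histogram bin counts for per-tumor burdens
#'
#' Bins a vector of non-negative counts into bins `0..max_bin` plus an
#' overflow bin, so burden histograms can be reported as plain count
#' tables. Bin counts always sum to the number of tumors.
#'
#' @param per_tumor_counts Non-negative integer vector.
#' @param max_bin Largest explicit bin.
#' @return Tibble with columns `bin` (character; `">max_bin"` for overflow)
#'   and `count`.
#' @examples
#' histogram_counts(c(0, 1, 1, 2), max_bin = 3)
#' @export
histogram_counts <- function(per_tumor_counts, max_bin = 15L) {
  if (any(per_tumor_counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  binned <- pmin(per_tumor_counts, max_bin + 1L)
  counts <- table(factor(binned, levels = 0:(max_bin + 1L)))
  tibble::tibble(bin = c(as.character(0:max_bin), paste0(">", max_bin)),
                 count = as.integer(counts))
}

#' Run the full profiling pipeline
#'
#' Executes read/simulate, repeat annotation, burden summaries, rule
#' evaluation and group-comparison statistics, and (when `out_dir` is set)
#' writes the report bundle: demography table, gene-frequency table,
#' repeat-indel table, per-tumor profile table, rule evaluations, burden
#' histograms (one count-per-bin TSV per burden type and group) and a JSON
#' bundle of full-precision test results. Any stage failure is re-raised
#' with the failing stage named. Identical configuration (and seed) yields
#' an identical bundle.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with elements `cohort`, `truth` (simulated
#'   runs only), `annotations`, `demography`, `burden_total`,
#'   `burden_uncommon`, `profiles`, `rule_evaluations`, `gene_frequency`,
#'   `indel_repeat`, `histograms`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  truth <- NULL
  refs <- NULL
  coh <- stage("cohort_model", {
    if (config$simulate) {
      sim <- generate_cohort(config$params)
      truth <- sim$truth
      refs <- sim$references
      sim$cohort
    } else if (!is.null(config$input_maf)) {
      read_mutation_table(config$input_maf, samples_path = config$samples)
    } else {
      read_minimal_vcf(config$input_vcf)
    }
  })
  if (nrow(coh$samples) == 0) {
    stop("cohort_model: cohort is empty", call. = FALSE)
  }
  if (is.null(refs)) {
    refs <- stage("hgvs_repeat", {
      if (!is.null(config$fasta)) {
        seqs <- Biostrings::readDNAStringSet(config$fasta)
        stats::setNames(as.character(seqs), names(seqs))
      } else {
        reference_fixtures(union(panel_genes(), unique(coh$mutations$gene)))
      }
    })
  }

  annotations <- stage("hgvs_repeat", annotate_cohort_repeats(coh, refs))
  demography <- stage("cohort_model", write_cohort_summary(coh))
  burden_total <- stage("burden_rules", cohort_burden(coh))
  burden_uncommon <- stage("burden_rules",
                           cohort_burden(coh, excluded_genes =
                                           common_crc_genes()))
  profiles <- stage("burden_rules", tumor_profiles(coh, annotations))
  rule_evals <- stage("burden_rules", {
    dplyr::bind_rows(lapply(config$rules, function(r) evaluate_rule(profiles,
                                                                    r)))
  })
  for (r in config$rules) {
    profiles[[paste0("predicted_", r$name, "_", r$k)]] <-
      predict_msi(profiles, r)
  }
  gene_freq <- stage("assoc_stats",
                     gene_frequency_table(coh, config$gene_sets))
  indel_rep <- stage("assoc_stats", indel_repeat_table(coh, annotations))

  hists <- stage("cli_report", {
    out <- list()
    for (metric in c("total", "uncommon", "hp_indels")) {
      for (g in c("MSS", "MSI_H")) {
        v <- profiles[[metric]][profiles$truth == g]
        if (all(is.na(v))) next
        out[[paste(metric, g, sep = "_")]] <-
          histogram_counts(v[!is.na(v)], config$max_bin)
      }
    }
    out
  })

  bundle <- list(cohort = coh, truth = truth, annotations = annotations,
                 demography = demography, burden_total = burden_total,
                 burden_uncommon = burden_uncommon, profiles = profiles,
                 rule_evaluations = rule_evals, gene_frequency = gene_freq,
                 indel_repeat = indel_rep, histograms = hists)

  if (!is.null(config$out_dir)) {
    stage("cli_report", write_bundle(bundle, config))
  }
  invisible(bundle)
}

write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  wt <- function(df, name) {
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    utils::write.table(df, out(name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  wt(bundle$demography, "demography.tsv")
  wt(bundle$burden_total, "burden_total.tsv")
  wt(bundle$burden_uncommon, "burden_uncommon.tsv")
  wt(bundle$annotations, "mutations_annotated.tsv")
  profiles <- bundle$profiles
  wt(profiles, "tumor_profiles.tsv")
  wt(bundle$rule_evaluations, "rule_evaluations.tsv")
  wt(bundle$gene_frequency, "gene_frequency.tsv")
  wt(bundle$indel_repeat, "indel_repeat.tsv")
  for (nm in names(bundle$histograms)) {
    wt(bundle$histograms[[nm]], paste0("histogram_", nm, ".tsv"))
  }
  gf <- bundle$gene_frequency
  jsonlite::write_json(
    list(gene_frequency = gf[, c("name", "p_fisher", "p_chisq")],
         rule_evaluations = bundle$rule_evaluations[
           , c("rule", "k", "tp", "fp", "tn", "fn",
               "sensitivity", "specificity")]),
    out("results.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
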