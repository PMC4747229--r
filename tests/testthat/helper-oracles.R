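# Independent brute-force oracles and small fixture builders.

# Exhaustive repeat-run oracle: enumerates every tandem interval of the
# sequence globally (O(n^3)), independent of the annotator's local run
# extension. Returns in_repeat for a del/dup span or an insertion.
oracle_in_repeat <- function(seq, kind, start, end = start, ins_seq = "") {
  n <- nchar(seq)
  s <- if (kind == "ins") ins_seq else substr(seq, start, end)
  for (L in seq_len(min(nchar(s), 6L))) {
    if (nchar(s) %% L != 0) next
    u <- substr(s, 1, L)
    if (strrep(u, nchar(s) / L) != s) next
    for (i in seq_len(n)) {
      max_m <- (n - i + 1) %/% L
      if (max_m < 2) next
      for (m in 2:max_m) {
        j <- i + m * L - 1
        if (substr(seq, i, j) != strrep(u, m)) next
        if (kind == "ins") {
          # insertion point `start` must be a copy boundary of the run
          if (start >= i - 1 && start <= j && (start - (i - 1)) %% L == 0) {
            return(TRUE)
          }
        } else {
          if (start >= i && end <= j && (start - i) %% L == 0) return(TRUE)
        }
      }
    }
  }
  FALSE
}

# All sequences of a given length over an alphabet.
all_sequences <- function(len, alphabet = c("A", "C")) {
  grid <- do.call(expand.grid, rep(list(alphabet), len))
  apply(grid, 1, paste, collapse = "")
}

# Direct-ratio Fisher oracle: enumerates the hypergeometric support with
# choose() ratios (no logs, no dhyper), point-probability two-sided rule.
oracle_fisher_support <- function(r1, r2, c1) {
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  x <- lo:hi
  probs <- choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  list(x = x, probs = probs)
}

oracle_fisher_p <- function(a, b, c, d) {
  sup <- oracle_fisher_support(a + b, c + d, a + c)
  p_obs <- sup$probs[sup$x == a]
  min(1, sum(sup$probs[sup$probs <= p_obs * (1 + 1e-7)]))
}

# Minimal labeled cohort: per-tumor burden vectors realized as mutations in
# dummy background genes, with the given MSI labels.
make_labeled_cohort <- function(mss_burdens, msih_burdens,
                                gene = "ATM") {
  ids <- c(sprintf("S%03d", seq_along(mss_burdens)),
           sprintf("H%03d", seq_along(msih_burdens)))
  status <- c(rep("MSS", length(mss_burdens)),
              rep("MSI_H", length(msih_burdens)))
  burdens <- c(mss_burdens, msih_burdens)
  rows <- lapply(seq_along(ids), function(i) {
    k <- burdens[i]
    if (k == 0) return(NULL)
    tibble::tibble(tumor_id = ids[i], gene = gene,
                   hgvs_c = sprintf("c.%dA>G", seq_len(k) * 3 + 1),
                   hgvs_p = NA_character_,
                   variant_class = "substitution")
  })
  cohort(dplyr::bind_rows(rows),
         samples = tibble::tibble(tumor_id = ids, msi_status = status))
}
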