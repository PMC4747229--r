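#' Gene sets and panel constants
#'
#' Named gene sets used throughout the burden and association analyses:
#' the nine genes most commonly mutated in colorectal cancer (excluded when
#' computing the "uncommon" mutation burden), the mTOR-pathway trio, and the
#' receptor tyrosine kinase (RTK) family genes covered by hotspot panels.
#'
#' @return A character vector of HUGO gene symbols.
#' @examples
#' common_crc_genes()
#' @name gene_sets
NULL

#' @rdname gene_sets
#' @export
common_crc_genes <- function() {
  c("APC", "BRAF", "CTNNB1", "FBXW7", "KRAS", "NRAS", "PIK3CA", "SMAD4",
    "TP53")
}

#' @rdname gene_sets
#' @export
mtor_genes <- function() {
  c("PIK3CA", "PTEN", "AKT1")
}

#' @rdname gene_sets
#' @export
rtk_genes <- function() {
  c("EGFR", "ERBB2", "ERBB4", "CSF1R", "FLT3", "KIT", "PDGFRA",
    "FGFR1", "FGFR2", "FGFR3", "MET", "RET")
}

# Additional panel members used as the simulator's background gene pool.
background_pool_genes <- function() {
  c(rtk_genes(),
    "ATM", "CDH1", "CDKN2A", "GNAS", "IDH1", "JAK3", "MLH1", "NOTCH1",
    "SMARCB1", "STK11", "VHL")
}

#' @rdname gene_sets
#' @export
panel_genes <- function() {
  sort(unique(c(common_crc_genes(), mtor_genes(), background_pool_genes())))
}

#' Recognized somatic variant classes
#'
#' The four mutation classes counted in burden summaries: non-synonymous
#' single-nucleotide substitutions, deletions, insertions/duplications, and
#' splice-site mutations.
#'
#' @return Character vector of class labels.
#' @export
mutation_classes <- function() {
  c("substitution", "deletion", "insertion_duplication", "splice")
}

#' Microsatellite assay loci
#'
#' Locus names of the PCR microsatellite instability panel: five
#' mononucleotide loci that determine the MSI-H call, and two pentanucleotide
#' loci used as specimen-identity controls (recorded, never counted).
#'
#' @return Character vector of locus names.
#' @export
msi_mono_loci <- function() {
  c("BAT-25", "BAT-26", "NR-21", "NR-24", "MONO-27")
}

#' @rdname msi_mono_loci
#' @export
msi_penta_loci <- function() {
  c("Penta C", "Penta D")
}

#' Example PTEN mutation calls from a colorectal hotspot-panel cohort
#'
#' A curated set of PTEN coding mutations observed across MSS and MSI-H
#' colorectal tumors, bundled as a worked example of panel output. The MSI-H
#' tumors carry eight indel variants, all in homopolymer or short-tandem-repeat
#' context (the two recurrent single-adenine deletions sit in (A)6 runs of
#' exons 7 and 8); all MSS PTEN mutations are single-base substitutions.
#' Replayed against [pten_reference()] these reproduce the expected repeat
#' annotations end to end.
#'
#' @return A tibble with columns `case`, `group` (`"MSS"`/`"MSI_H"`),
#'   `hgvs_p`, `hgvs_c`, `repeat_region` (reported repeat context, `""` for
#'   substitutions) and `exon`.
#' @export
pten_mutations <- function() {
  tibble::tribble(
    ~case,     ~group,  ~hgvs_p,         ~hgvs_c,           ~repeat_region,        ~exon,
    "131",     "MSS",   "p.Y177Ter",     "c.531T>G",        "",                    6L,
    "133",     "MSS",   "p.R233Ter",     "c.697C>T",        "",                    7L,
    "181",     "MSS",   "p.A126T",       "c.376G>A",        "",                    5L,
    "48",      "MSI_H", "p.T319Ter",     "c.954_957del",    "delTACT of (TACT)2",  8L,
    "143",     "MSI_H", "p.N323Mfs*21",  "c.968delA",       "delA of (A)6",        8L,
    "218",     "MSI_H", "p.L325R",       "c.974T>G",        "",                    8L,
    "218",     "MSI_H", "p.K267Rfs*9",   "c.800delA",       "delA of (A)6",        7L,
    "240",     "MSI_H", "p.R234W",       "c.700C>T",        "",                    7L,
    "264",     "MSI_H", "p.I122N",       "c.365T>A",        "",                    5L,
    "264",     "MSI_H", "p.R130Q",       "c.359G>A",        "",                    NA_integer_,
    "264",     "MSI_H", "p.N323Mfs*21",  "c.968delA",       "delA of (A)6",        8L,
    "273",     "MSI_H", "p.S10I",        "c.29G>T",         "",                    1L,
    "MSIH22",  "MSI_H", "p.Y178Ffs*6",   "c.531_532dupTT",  "dupTT",               6L,
    "MSIH22",  "MSI_H", "p.K267Rfs*9",   "c.800delA",       "delA of (A)6",        7L,
    "MSIH24",  "MSI_H", "p.K267Rfs*9",   "c.800delA",       "delA of (A)6",        7L,
    "MSIH24",  "MSI_H", "p.N323Mfs*21",  "c.968delA",       "delA of (A)6",        8L
  )
}

#' Tumor-level gene mutation counts for a 113 MSS / 29 MSI-H cohort
#'
#' Number of tumors carrying at least one mutation in each panel gene, per
#' MSI group, for the reference cohort the simulator emulates (113 MSS and
#' 29 MSI-H tumors). These counts seed the simulator's default per-gene
#' tumor-level mutation probabilities.
#'
#' @return A tibble with columns `gene`, `mss_n` (of 113), `msih_n` (of 29).
#' @export
gene_mutation_counts <- function() {
  tibble::tribble(
    ~gene,     ~mss_n, ~msih_n,
    "APC",     53L,    10L,
    "BRAF",    6L,     10L,
    "CTNNB1",  6L,     1L,
    "FBXW7",   6L,     4L,
    "KRAS",    52L,    9L,
    "NRAS",    5L,     3L,
    "PIK3CA",  17L,    10L,
    "SMAD4",   12L,    0L,
    "TP53",    71L,    9L,
    "AKT1",    1L,     1L,
    "PTEN",    3L,     8L
  )
}

#' Default gene sets for the group-comparison frequency table
#'
#' One singleton set per profiled gene plus the mTOR-pathway membership set
#' (PIK3CA, PTEN and/or AKT1, counted at tumor level) and the RTK family set.
#'
#' @return Named list of character vectors of gene symbols.
#' @export
default_gene_sets <- function() {
  sets <- as.list(gene_mutation_counts()$gene)
  names(sets) <- gene_mutation_counts()$gene
  sets$mTOR <- mtor_genes()
  sets$RTK <- rtk_genes()
  sets
}
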