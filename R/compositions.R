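#' @useDynLib jointsnv, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median runif setNames
#' @importFrom utils write.table
"_PACKAGE"

# Canonical allele order; all composition bookkeeping uses indices into this.
ALLELES <- c("A", "C", "G", "T")

# Composition universe in canonical order: singletons, then pairs, then
# triples, each block lexicographic in A<C<G<T.  The first 10 entries (one or
# two alleles) form the universe allowed for the diploid normal sample; all 14
# are allowed for tumour samples.
COMP_MEMBERS <- local({
  sets <- list()
  for (size in 1:3) {
    idx <- utils::combn(4L, size)
    for (j in seq_len(ncol(idx))) sets[[length(sets) + 1L]] <- idx[, j]
  }
  sets
})
COMP_LABELS <- vapply(COMP_MEMBERS, function(m) paste(ALLELES[m], collapse = ""),
                      character(1))
COMP_SIZES <- lengths(COMP_MEMBERS)
# 14 x 4 membership matrix (1 = allele present)
COMP_MATRIX <- t(vapply(COMP_MEMBERS, function(m) as.integer(seq_len(4) %in% m),
                        integer(4)))
dimnames(COMP_MATRIX) <- list(COMP_LABELS, ALLELES)

N_NORMAL_COMPS <- 10L
N_TUMOR_COMPS <- 14L

#' Enumerate allelic compositions
#'
#' An allelic composition is the set of distinct alleles present at a locus in
#' a sample; it generalises a genotype to impure, non-diploid tumour samples.
#' The normal sample is modelled as pure and diploid, so it may carry one or
#' two alleles (10 compositions); tumour samples may carry up to three
#' (`2^4 - 2 = 14` compositions: every non-empty subset of {A,C,G,T} except
#' the full set and the empty set).
#'
#' @param max_alleles Maximum number of alleles per composition: 2 for the
#'   normal universe, 3 for the tumour universe.
#' @return Character vector of composition labels (e.g. `"A"`, `"AC"`,
#'   `"ACG"`) in canonical order: by size, then lexicographically with
#'   A < C < G < T.  Length 10 for `max_alleles = 2`, 14 for `max_alleles = 3`.
#' @examples
#' enumerate_compositions(2)
#' enumerate_compositions(3)
#' @export
enumerate_compositions <- function(max_alleles) {
  if (!max_alleles %in% c(2L, 3L)) {
    stop("max_alleles must be 2 (normal universe) or 3 (tumour universe)")
  }
  COMP_LABELS[COMP_SIZES <= max_alleles]
}

#' Alleles of a composition
#'
#' @param comp Composition label (e.g. `"AC"`) or index into the canonical
#'   universe.
#' @return Character vector of member alleles.
#' @export
composition_alleles <- function(comp) {
  ALLELES[COMP_MEMBERS[[comp_index(comp)]]]
}

# Resolve a composition given as label or index to its canonical index.
comp_index <- function(comp) {
  if (is.character(comp)) {
    i <- match(comp, COMP_LABELS)
    if (is.na(i)) stop("unknown allelic composition: ", comp)
    return(i)
  }
  i <- as.integer(comp)
  if (i < 1L || i > N_TUMOR_COMPS) stop("composition index out of range: ", i)
  i
}

# Resolve an allele given as "A".."T" or index 1..4.
allele_index <- function(allele) {
  if (is.character(allele)) {
    i <- match(allele, ALLELES)
    if (is.na(i)) stop("unknown allele: ", allele)
    return(i)
  }
  as.integer(allele)
}
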