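#' Tile the sequence into 5-SNP marker windows
#'
#' Marker loci are haplotypes of groups of five consecutive SNP sites; the
#' different haplotypic combinations per window are treated as different
#' alleles, giving at most 2^5 = 32 alleles per locus. Windows are fixed
#' consecutive tiles of the sequence (polymorphic or not), so a 10 kb
#' sequence yields 2,000 candidate loci.
#'
#' @param seq_len sequence length in sites; must be a multiple of 5.
#' @return A data frame with one row per locus: `locus` (1-based index),
#'   `start`, `end` (0-based, half-open site range).
#' @examples
#' build_locus_map(15)  # windows [0,5), [5,10), [10,15)
#' @export
build_locus_map <- function(seq_len) {
  stopifnot(is_count(seq_len), seq_len >= 5)
  if (seq_len %% 5 != 0)
    stop("seq_len must be divisible by 5")
  w <- seq_len %/% 5
  data.frame(locus = seq_len(w), start = 5L * (seq_len(w) - 1L),
             end = 5L * seq_len(w))
}

#' Construct a genotype matrix of marker allele codes
#'
#' Builds, for every individual and locus, the pair of 5-bit allele codes
#' (0-31) of its two window haplotypes; the leftmost (lowest-coordinate)
#' site is the most significant bit, so bits b0..b4 in genomic order encode
#' allele `sum(b_i * 2^(4-i))`.
#'
#' @param metapop a (usually sexed) `metapop` object.
#' @param map a locus map from [build_locus_map()]; defaults to the map of
#'   the full sequence.
#' @return A `geno_matrix`: list with integer matrices `a1`, `a2`
#'   (individuals x loci, codes 0-31), integer `deme`, character `sex`, and
#'   the locus `map`.
#' @export
encode_genotypes <- function(metapop, map = NULL) {
  L <- nrow(metapop$demes[[1]])
  map <- map %||% build_locus_map(L)
  if (max(map$end) > L)
    stop("locus map extends beyond the sequence")
  a1 <- list()
  a2 <- list()
  for (d in seq_along(metapop$demes)) {
    codes <- encode_windows_cpp(metapop$demes[[d]])[map$locus, , drop = FALSE]
    n <- ncol(codes) %/% 2
    a1[[d]] <- t(codes[, 2 * seq_len(n) - 1, drop = FALSE])
    a2[[d]] <- t(codes[, 2 * seq_len(n), drop = FALSE])
  }
  sizes <- deme_sizes(metapop)
  sex <- if (is.null(metapop$sexes)) rep(NA_character_, sum(sizes))
         else unlist(metapop$sexes)
  geno_matrix(do.call(rbind, a1), do.call(rbind, a2),
              deme = rep(seq_along(sizes), sizes), sex = sex, map = map)
}

#' Genotype matrix constructor
#'
#' Container for multiallelic marker genotypes: two allele codes in 0-31 per
#' individual and locus, plus deme and sex labels. Built by
#' [encode_genotypes()] from a simulation, or directly from externally
#' supplied codes (see [read_genotypes_tsv()]).
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele codes, the
#'   first and second haplotype respectively.
#' @param deme integer deme label per individual (1-based, consecutive).
#' @param sex character `"F"`/`"M"` per individual, or `NA`.
#' @param map optional locus map (see [build_locus_map()]).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(a1, a2, deme, sex = NULL, map = NULL) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  n <- nrow(a1)
  stopifnot(identical(dim(a1), dim(a2)), length(deme) == n)
  if (n > 0 && ncol(a1) > 0)
    stopifnot(min(a1, a2) >= 0, max(a1, a2) <= 31)
  sex <- sex %||% rep(NA_character_, n)
  stopifnot(length(sex) == n)
  structure(list(a1 = a1, a2 = a2, deme = as.integer(deme),
                 sex = as.character(sex), map = map),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("Genotype matrix: ", nrow(x$a1), " individuals x ", ncol(x$a1),
      " loci, ", length(unique(x$deme)), " deme(s)\n", sep = "")
  invisible(x)
}

n_loci <- function(gm) ncol(gm$a1)

n_demes <- function(gm) max(gm$deme)

#' Decode a 5-bit marker allele
#'
#' Inverse of the window encoding of [encode_genotypes()].
#'
#' @param code integer vector of allele codes in 0-31.
#' @return A matrix with 5 columns of 0/1 site states in genomic order
#'   (leftmost site first).
#' @export
decode_allele <- function(code) {
  stopifnot(all(code >= 0), all(code <= 31))
  t(vapply(as.integer(code),
           function(a) as.integer(bitwAnd(bitwShiftR(a, 4:0), 1L)),
           integer(5)))
}

#' Loci segregating in the pooled metapopulation
#'
#' @param gm a `geno_matrix`.
#' @return Integer vector, in genomic order, of loci carrying at least two
#'   distinct allele codes across all individuals and demes.
#' @export
segregating_loci <- function(gm) {
  if (nrow(gm$a1) == 0) return(integer(0))
  r1 <- gm$a1[1, ]
  poly <- colSums(gm$a1 != rep(r1, each = nrow(gm$a1))) +
    colSums(gm$a2 != rep(r1, each = nrow(gm$a2)))
  which(poly > 0)
}

#' Select the managed marker panel
#'
#' Takes every `every_nth` locus of the segregating list, starting at its
#' first element, in genomic order. With roughly 1,200 segregating loci this
#' gives the study's 12 managed markers (`every_nth = 100`, loci-of-interest
#' scenario) or 120 markers (`every_nth = 10`, whole-genome scenario).
#'
#' @param segregating integer vector of segregating locus indices, as from
#'   [segregating_loci()].
#' @param every_nth positive spacing between retained loci.
#' @param scope measurement scope this panel is intended for: `"managed"`
#'   (statistics on the panel itself) or `"all"` (whole-genome statistics).
#' @return A `managed_set`: list with `loci`, `every_nth` and `scope`.
#' @export
select_managed <- function(segregating, every_nth, scope = c("managed", "all")) {
  scope <- match.arg(scope)
  stopifnot(is_count(every_nth), every_nth >= 1)
  if (length(segregating) == 0)
    stop("no segregating loci to select from")
  loci <- segregating[seq(1, length(segregating), by = every_nth)]
  structure(list(loci = as.integer(loci), every_nth = as.integer(every_nth),
                 scope = scope),
            class = "managed_set")
}

#' Marker density in markers per Morgan
#'
#' The genetic map length of the sequence is `(seq_len - 1) * rec` Morgans
#' under a per-boundary recombination probability `rec`; the density of a
#' panel of `n_markers` over that map is their ratio. At c = 1e-6 over 10 kb
#' the study's 12- and 120-marker panels give 1,200 and 12,000 markers per
#' Morgan.
#'
#' @param n_markers number of markers in the panel.
#' @param seq_len sequence length in sites.
#' @param rec per-boundary recombination probability.
#' @return Markers per Morgan.
#' @export
marker_density <- function(n_markers, seq_len, rec) {
  stopifnot(rec > 0, seq_len > 1)
  n_markers / ((seq_len - 1) * rec)
}

# subset a genotype matrix to a set of loci (keeps original indices in map)
subset_loci <- function(gm, loci) {
  map <- if (is.null(gm$map)) NULL else gm$map[loci, , drop = FALSE]
  geno_matrix(gm$a1[, loci, drop = FALSE], gm$a2[, loci, drop = FALSE],
              gm$deme, gm$sex, map = map)
}
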