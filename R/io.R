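#' Write marker genotypes to TSV
#'
#' One row per individual: `deme`, `individual`, `sex`, then a pair of
#' allele-code columns per locus named `L<locus>.<start>.<end>.a` /
#' `...b`, the window coordinates 0-based and half-open.
#'
#' @param gm a `geno_matrix` with a locus map.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_genotypes_tsv <- function(gm, path) {
  map <- gm$map %||% data.frame(locus = seq_len(n_loci(gm)),
                                start = NA_integer_, end = NA_integer_)
  base <- sprintf("L%d.%d.%d", map$locus, map$start, map$end)
  out <- data.frame(deme = gm$deme, individual = seq_len(nrow(gm$a1)),
                    sex = gm$sex, check.names = FALSE)
  geno <- matrix(NA_integer_, nrow(gm$a1), 2 * n_loci(gm))
  geno[, 2 * seq_len(n_loci(gm)) - 1] <- gm$a1
  geno[, 2 * seq_len(n_loci(gm))] <- gm$a2
  colnames(geno) <- as.vector(rbind(paste0(base, ".a"), paste0(base, ".b")))
  utils::write.table(cbind(out, geno), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read marker genotypes from TSV
#'
#' Inverse of [write_genotypes_tsv()]; also accepts externally produced
#' files in the same layout.
#'
#' @param path TSV file.
#' @return A `geno_matrix`.
#' @export
read_genotypes_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  acols <- grep("\\.a$", names(df))
  bcols <- grep("\\.b$", names(df))
  stopifnot(length(acols) == length(bcols), length(acols) >= 1)
  parts <- do.call(rbind, strsplit(sub("\\.a$", "", names(df)[acols]), "\\."))
  map <- data.frame(locus = as.integer(sub("^L", "", parts[, 1])),
                    start = suppressWarnings(as.integer(parts[, 2])),
                    end = suppressWarnings(as.integer(parts[, 3])))
  geno_matrix(as.matrix(df[, acols]), as.matrix(df[, bcols]),
              deme = df$deme, sex = df$sex, map = map)
}

#' Write founder haplotypes as VCF 4.2
#'
#' One record per segregating site on contig `"sim"` (1-based positions),
#' phased `GT` fields, ancestral state as REF. Sample names are
#' `d<deme>i<individual>`.
#'
#' @param metapop a `metapop`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_founders_vcf <- function(metapop, path) {
  haps <- do.call(cbind, metapop$demes)
  cnt <- site_counts_cpp(haps)
  seg <- which(cnt > 0 & cnt < ncol(haps))
  sizes <- deme_sizes(metapop)
  ids <- unlist(lapply(seq_along(sizes),
                       function(d) sprintf("d%di%d", d, seq_len(sizes[d]))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=sim>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  m <- matrix(as.integer(haps[seg, , drop = FALSE]), nrow = length(seg))
  n <- ncol(m) %/% 2
  gt <- matrix(paste(m[, 2 * seq_len(n) - 1, drop = FALSE],
                     m[, 2 * seq_len(n), drop = FALSE], sep = "|"),
               nrow = length(seg))
  writeLines(paste("sim", seg, ".", "A", "T", ".", "PASS", ".", "GT",
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Read phased biallelic genotypes from VCF
#'
#' Builds marker loci from groups of five consecutive VCF records (requires
#' the `vcfR` package). Intended for externally supplied genotypes entering
#' the statistics and optimisation stages; records beyond the last complete
#' group of five are dropped.
#'
#' @param path a VCF file with phased biallelic `GT` fields.
#' @param deme integer deme label per sample (default: one deme).
#' @param sex optional `"F"`/`"M"` per sample.
#' @return A `geno_matrix`.
#' @export
read_genotypes_vcf <- function(path, deme = NULL, sex = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotypes_vcf() requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  if (any(!grepl("^[01]\\|[01]$", gt)))
    stop("VCF must contain phased biallelic genotypes")
  h1 <- matrix(as.integer(substr(gt, 1, 1)), nrow(gt), ncol(gt))
  h2 <- matrix(as.integer(substr(gt, 3, 3)), nrow(gt), ncol(gt))
  W <- nrow(h1) %/% 5
  if (W == 0) stop("fewer than five sites in the VCF")
  keep <- seq_len(5 * W)
  pow <- 2^(4:0)
  code <- function(h) t(matrix(pow %*% matrix(h[keep, ], nrow = 5), W))
  geno_matrix(code(h1), code(h2),
              deme = deme %||% rep(1L, ncol(gt)), sex = sex,
              map = data.frame(locus = seq_len(W), start = NA, end = NA))
}

#' Read a study configuration file
#'
#' YAML or JSON (by extension); fields override the chosen profile's
#' defaults.
#'
#' @param path configuration file.
#' @param profile base profile to override (default `"paper"`, or the
#'   file's own `profile` field).
#' @return A `study_config`.
#' @export
read_study_config <- function(path, profile = NULL) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  profile <- profile %||% vals$profile %||% "paper"
  vals$profile <- NULL
  if (!is.null(vals$schedule))
    vals$schedule <- do.call(anneal_schedule, vals$schedule)
  if (!is.null(vals$scenarios))
    vals$scenarios <- lapply(vals$scenarios, function(sc)
      list(every_nth = as.integer(sc$every_nth),
           scope = sc$scope %||% "managed"))
  do.call(study_profile, c(list(profile = profile), vals))
}

#' Write a contribution plan as TSV
#'
#' Aggregated mating entries: `natal_deme`, `sire`, `dam`, `dest_deme`,
#' `n_offspring`.
#'
#' @param plan a `contribution_plan`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_plan_tsv <- function(plan, path) {
  df <- as.data.frame(plan)
  names(df) <- c("natal_deme", "sire", "dam", "dest_deme", "n_offspring")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contribution plan from TSV
#'
#' @param path a file written by [write_plan_tsv()].
#' @param gm the parental `geno_matrix` the plan refers to.
#' @return A `contribution_plan`.
#' @export
read_plan_tsv <- function(path, gm) {
  df <- read.delim(path)
  slot <- df[rep(seq_len(nrow(df)), df$n_offspring), ]
  slot <- slot[order(slot$dest_deme), ]
  D <- n_demes(gm)
  N <- nrow(slot) %/% D
  new_plan(slot$dest_deme, slot$natal_deme, slot$sire, slot$dam, gm,
           deme_size = N, migrants = sum(slot$natal_deme != slot$dest_deme))
}
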