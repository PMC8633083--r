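# Standard-format input/output: block extraction from phased, polarized
# VCF data, and TSV/JSON serialisation of datasets and tables.
#
# Coordinates are 1-based inclusive externally (VCF convention); block
# membership is computed half-open 0-based internally, converted at the
# boundary only. A variant at the anchor itself belongs to no block.

#' Extract blockwise derived-allele data from a phased VCF
#'
#' Reads biallelic SNPs around an anchor coordinate, polarizes them by the
#' ancestral allele (the `AA` INFO tag, optionally a lookup table), and
#' returns, for each of `B` non-overlapping blocks of `l` bases split
#' evenly left and right of the anchor, the matrix of per-haplotype derived
#' indicators. Sites that are multiallelic, not SNPs, unpolarizable,
#' unphased, or carry missing genotypes in the chosen samples are dropped
#' and counted in the log.
#'
#' @param vcf Path to a VCF file (plain or gzipped).
#' @param chrom Contig name.
#' @param anchor 1-based position of the putative sweep target.
#' @param geometry A [block_geometry()].
#' @param samples Optional character vector of sample names to keep.
#' @param ancestral Optional named character vector `position -> allele`
#'   used when the `AA` tag is absent.
#' @param allow_unphased Treat `/`-separated genotypes as phased (off by
#'   default; otherwise unphased genotypes are an error).
#' @return List with `blocks` (one 0/1 matrix, variants x haplotypes, per
#'   geometry row), `geometry`, `n_haplotypes`, and a `log` of dropped-site
#'   counts.
#' @export
extract_blocks <- function(vcf, chrom, anchor, geometry, samples = NULL,
                           ancestral = NULL, allow_unphased = FALSE) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt[, -1L, drop = FALSE]
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(gt))
    if (length(miss)) stop("samples not in VCF: ", paste(miss, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  keep_chrom <- fix[, "CHROM"] == chrom
  fix <- fix[keep_chrom, , drop = FALSE]
  gt <- gt[keep_chrom, , drop = FALSE]
  pos <- as.integer(fix[, "POS"])
  log <- c(total = length(pos), multiallelic = 0L, not_snp = 0L,
           no_ancestral = 0L, mismatched_ancestral = 0L, unphased = 0L,
           missing_gt = 0L, at_anchor = 0L, outside = 0L, used = 0L)
  l <- attr(geometry, "l")
  nb_side <- attr(geometry, "B") / 2L
  # block index: right block i covers anchor + ((i-1)l, il]; left block i
  # covers anchor - [il, (i-1)l) (1-based inclusive on both sides)
  block_of <- function(p) {
    if (p == anchor) return(NA_integer_)
    off <- p - anchor
    if (off > 0) {
      i <- ceiling(off / l)
      if (i > nb_side) return(NA_integer_)
      which(geometry$side == "right")[i]
    } else {
      i <- ceiling((-off) / l)
      if (i > nb_side) return(NA_integer_)
      which(geometry$side == "left")[i]
    }
  }
  nh <- NULL
  rows <- vector("list", nrow(geometry))
  for (z in seq_along(pos)) {
    ref <- fix[z, "REF"]; alt <- fix[z, "ALT"]
    if (is.na(alt) || grepl(",", alt, fixed = TRUE)) { log["multiallelic"] <- log["multiallelic"] + 1L; next }
    if (nchar(ref) != 1L || nchar(alt) != 1L) { log["not_snp"] <- log["not_snp"] + 1L; next }
    aa <- NA_character_
    m <- regmatches(fix[z, "INFO"],
                    regexpr("(?:^|;)AA=([A-Za-z])", fix[z, "INFO"], perl = TRUE))
    if (length(m)) aa <- toupper(sub(".*AA=", "", m))
    if (is.na(aa) && !is.null(ancestral)) aa <- toupper(ancestral[as.character(pos[z])])
    if (is.na(aa)) { log["no_ancestral"] <- log["no_ancestral"] + 1L; next }
    if (!(aa %in% c(ref, alt))) { log["mismatched_ancestral"] <- log["mismatched_ancestral"] + 1L; next }
    g <- gt[z, ]
    g <- sub(":.*", "", g)
    if (anyNA(g) || any(grepl("\\.", g))) {
      log["missing_gt"] <- log["missing_gt"] + 1L; next
    }
    phased <- grepl("|", g, fixed = TRUE)
    if (!all(phased)) {
      if (!allow_unphased) stop("unphased genotype at position ", pos[z],
                                "; set allow_unphased = TRUE to force")
      log["unphased"] <- log["unphased"] + 1L
    }
    hap <- as.integer(unlist(strsplit(g, "[|/]")))
    if (is.null(nh)) nh <- length(hap)
    derived <- if (aa == ref) hap else 1L - hap   # swapped REF/ALT: complement
    bi <- block_of(pos[z])
    if (is.na(bi)) {
      log[if (pos[z] == anchor) "at_anchor" else "outside"] <-
        log[if (pos[z] == anchor) "at_anchor" else "outside"] + 1L
      next
    }
    rows[[bi]] <- c(rows[[bi]], list(derived))
    log["used"] <- log["used"] + 1L
  }
  if (is.null(nh)) nh <- 2L * ncol(gt)
  blocks <- lapply(rows, function(rr) {
    if (is.null(rr)) matrix(0L, 0L, nh) else do.call(rbind, rr)
  })
  list(blocks = blocks, geometry = geometry, n_haplotypes = nh, log = log)
}

## ---- dataset serialisation ---------------------------------------------

#' Write / read a blockwise replicate dataset
#'
#' The dataset is written as TSV (one row per block) with a JSON sidecar
#' (`<path>.json`) holding the generating parameters, so a round trip
#' restores both the table and its provenance.
#'
#' @param ds A `replicate_dataset` from [simulate_blocks()].
#' @param path Output TSV path.
#' @return `path`, invisibly (writer); the dataset (reader).
#' @export
write_replicate_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "replicate_dataset"))
  utils::write.table(as.data.frame(ds), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- attr(ds, "params"); m <- attr(ds, "mut")
  meta <- list(Ne = p$Ne, s = p$s, r = p$r, Ta = p$Ta,
               theta = m$theta, k_max = m$k_max,
               mode = attr(ds, "mode"), n = attr(ds, "n"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_replicate_dataset
#' @export
read_replicate_dataset <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- sweep_params(meta$Ne, meta$s, meta$r, meta$Ta)
  attr(tab, "params") <- params
  attr(tab, "mut") <- mutation_model(meta$theta, meta$k_max)
  attr(tab, "mode") <- meta$mode
  attr(tab, "n") <- as.integer(meta$n)
  class(tab) <- c("replicate_dataset", "data.frame")
  tab
}

#' Write a bSFS table as TSV with metadata header
#'
#' @param x A `bsfs_table`.
#' @param path Output path.
#' @export
write_bsfs_table <- function(x, path) {
  df <- bsfs_as_data_frame(x)
  hdr <- sprintf("# theta=%g k_max=%d alpha=%s Ta=%s model=%s",
                 attr(x, "theta"), attr(x, "k_max"),
                 format(attr(x, "alpha")), format(attr(x, "Ta")),
                 attr(x, "model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
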