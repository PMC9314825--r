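#' Read a sample sheet
#'
#' The sample sheet assigns every sequenced individual a role in the
#' parentage analysis (`hybrid_candidate`, `candidate_parent` or
#' `reference_panel`), a photosynthetic group label (`C3`, `C3+C4`, `C4`),
#' and, for hybrids, the identity of the known mother (the plant the seed
#' was collected from).
#'
#' @param path CSV file with columns `sample_id`, `role`, `group` and
#'   optionally `mother_id`.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_sample_sheet(sheet)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses GT and, where present, per-sample DP and GQ annotations from a
#' VCF v4.x file. Multi-allelic records are retained with all alternate
#' alleles; missing genotypes (`./.`) are encoded as the missing state.
#' Input site order is preserved. No filtering is applied here.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param sample_sheet a data frame as returned by [read_sample_sheet()],
#'   or a path to one. Every sample named in the VCF must appear in it.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, sample_sheet) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  sample_sheet <- validate_sample_sheet(sample_sheet)
  if (!file.exists(path)) abort(paste0("no such VCF file: ", path))

  vcf_samples <- vcf_header_samples(path)
  unknown <- setdiff(vcf_samples, sample_sheet$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("VCF sample(s) not in sample sheet: ", paste(unknown, collapse = ", ")))
  }
  samples <- sample_sheet[match(vcf_samples, sample_sheet$sample_id), , drop = FALSE]

  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    sites <- tibble::tibble(chrom = character(), pos = integer(), id = character(),
                            ref = character(), alt = character(), qual = double(),
                            is_indel = logical())
    return(geno_matrix(sites, samples,
                       matrix(NA_integer_, 0, nrow(samples)),
                       matrix(NA_integer_, 0, nrow(samples))))
  }

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    abort(sprintf("malformed VCF record %d (CHROM=%s POS=%s): non-numeric position",
                  bad, fix[bad, "CHROM"], fix[bad, "POS"]))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  alt_len_ok <- function(a) {
    if (a == ".") return(TRUE)
    all(nchar(strsplit(a, ",", fixed = TRUE)[[1]]) == 1)
  }
  is_indel <- nchar(ref) != 1L | !vapply(alt, alt_len_ok, logical(1), USE.NAMES = FALSE)
  sites <- tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = pos,
    id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref = ref,
    alt = alt,
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    is_indel = is_indel
  )

  gt <- extract_fmt(v, "GT", numeric = FALSE)
  if (is.null(gt)) abort(paste0("VCF has no GT field: ", path))
  gt <- align_fmt(gt, nrow(sites), vcf_samples)
  a1 <- suppressWarnings(matrix(as.integer(sub("[/|].*$", "", gt)), nrow(gt), ncol(gt)))
  a2v <- sub("^[^/|]*[/|]", "", gt)
  no_sep <- !grepl("[/|]", gt)
  a2v[no_sep] <- gt[no_sep]  # haploid call: duplicate the single allele
  a2 <- suppressWarnings(matrix(as.integer(a2v), nrow(gt), ncol(gt)))

  dp <- extract_fmt(v, "DP", numeric = TRUE)
  gq <- extract_fmt(v, "GQ", numeric = TRUE)
  dp <- if (is.null(dp)) NULL else align_fmt(dp, nrow(sites), vcf_samples)
  gq <- if (is.null(gq)) NULL else align_fmt(gq, nrow(sites), vcf_samples)

  geno_matrix(sites, samples, a1, a2, gq = gq, dp = dp)
}

# sample names from the #CHROM header line, without parsing the whole file
vcf_header_samples <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) abort(paste0("no #CHROM header line in VCF: ", path))
    if (startsWith(line, "#CHROM")) {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(f) < 10) abort(paste0("VCF has no sample columns: ", path))
      return(f[-(1:9)])
    }
    if (!startsWith(line, "#")) abort(paste0("malformed VCF header in: ", path))
  }
}

extract_fmt <- function(v, element, numeric) {
  out <- tryCatch(
    vcfR::extract.gt(v, element = element, as.numeric = numeric),
    error = function(e) NULL
  )
  out
}

align_fmt <- function(m, ns, sample_names) {
  if (!is.matrix(m)) m <- matrix(m, nrow = ns)
  m[, sample_names, drop = FALSE]
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits GT, DP and GQ per-sample fields. Genotypes are written unphased
#' (`a/b`), missing calls as `./.`; absent annotations become `.`.
#'
#' @param gm a [geno_matrix()].
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hybridtyper",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            gm$samples$sample_id), collapse = "\t")
  )
  ns <- n_sites(gm)
  if (ns == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  gt <- matrix(sprintf("%s/%s",
                       ifelse(is.na(gm$allele1), ".", gm$allele1),
                       ifelse(is.na(gm$allele2), ".", gm$allele2)),
               ns, n_samples(gm))
  fmt_num <- function(m) ifelse(is.na(m), ".", format(m, trim = TRUE, scientific = FALSE))
  cell <- matrix(paste(gt, fmt_num(gm$dp), fmt_num(gm$gq), sep = ":"), ns, n_samples(gm))
  body <- paste(
    gm$sites$chrom, gm$sites$pos, gm$sites$id, gm$sites$ref, gm$sites$alt,
    ifelse(is.na(gm$sites$qual), ".", format(gm$sites$qual, trim = TRUE, scientific = FALSE)),
    ".", ".", "GT:DP:GQ",
    apply(cell, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the sample sheet of a genotype matrix as CSV
#'
#' @param gm a [geno_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(gm, path) {
  keep <- intersect(c("sample_id", "role", "group", "mother_id"), names(gm$samples))
  readr::write_csv(gm$samples[, keep], path)
  invisible(path)
}
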