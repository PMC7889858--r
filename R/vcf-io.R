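#' Read a multi-sample VCF file
#'
#' Parses a VCF v4.2 text file into a light columnar representation: one row
#' per record plus per-sample genotype (GT) and allelic depth (AD) matrices.
#' Only the INFO keys used downstream (FS, QD, DP) are extracted; everything
#' else in INFO is ignored. Sample order follows the `#CHROM` header line.
#'
#' Records whose AD length disagrees with the allele count, or whose FORMAT
#' lacks AD, are retained but every affected call is marked missing, so they
#' fall out later as "no data" and the filter accounting stays in one place.
#' Phasing is ignored: `0|1` and `0/1` carry the same allele-index pair.
#'
#' @param file Path to an uncompressed VCF file, or a connection.
#' @param chunk_size Number of record lines read per chunk. The file is never
#'   held in memory as a whole; chunks are parsed and appended.
#' @return An object of class `ase_vcf`: a list with elements
#'   \describe{
#'     \item{samples}{character vector of sample names}
#'     \item{sites}{data.frame with columns chrom, pos, id, ref, alt
#'       (comma-joined), n_alts, qual, filter, fs, qd, dp, line}
#'     \item{gt1, gt2}{integer matrices of allele indices (NA = missing call)}
#'     \item{ad}{character matrix of raw AD strings}
#'     \item{ref_ad, alt_ad}{integer matrices of the first two AD entries
#'       (NA where AD is absent or malformed)}
#'     \item{ad_sum}{integer matrix of total AD per call}
#'     \item{missing}{logical matrix: call unusable (no GT, no AD, or AD
#'       length mismatch)}
#'   }
#' @export
read_vcf <- function(file, chunk_size = 5000L) {
  acc <- NULL
  read_vcf_chunked(file, function(chunk) {
    acc <<- if (is.null(acc)) chunk else rbind_vcf(acc, chunk)
  }, chunk_size = chunk_size)
  if (is.null(acc)) stop("VCF contains a header but no records")
  acc
}

#' Stream a VCF file in fixed-size chunks
#'
#' Reads the file chunk by chunk and invokes `callback` on each parsed
#' `ase_vcf` chunk, keeping memory constant in the number of records. This is
#' the primitive behind [read_vcf()]; use it directly for large files.
#'
#' @inheritParams read_vcf
#' @param callback Function of one argument, called with each chunk (an
#'   `ase_vcf` object covering `chunk_size` records or fewer).
#' @return Invisibly, the header sample names.
#' @export
read_vcf_chunked <- function(file, callback, chunk_size = 5000L) {
  con <- if (inherits(file, "connection")) file else {
    f <- file(file, open = "rt")
    on.exit(close(f), add = TRUE)
    f
  }
  samples <- NULL
  line_no <- 0L
  # header
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("missing #CHROM header line: not a VCF file")
    line_no <- line_no + 1L
    if (startsWith(ln, "#CHROM")) {
      cols <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(cols) < 10L)
        stop("#CHROM line declares no samples (FORMAT/sample columns required)")
      samples <- cols[-(1:9)]
      break
    }
    if (!startsWith(ln, "##"))
      stop(sprintf("line %d: expected '##' meta line or '#CHROM' header", line_no))
  }
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (length(lines) == 0L) break
    chunk <- parse_vcf_records(lines, samples, line_offset = line_no)
    line_no <- line_no + length(lines)
    callback(chunk)
  }
  invisible(samples)
}

# Parse a block of record lines into an ase_vcf chunk.
parse_vcf_records <- function(lines, samples, line_offset = 0L) {
  ns <- length(samples)
  n <- length(lines)
  sp <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(sp)
  bad <- which(lens != 9L + ns)
  if (length(bad))
    stop(sprintf("line %d: %d columns, expected %d (9 fixed + %d samples)",
                 line_offset + bad[1], lens[bad[1]], 9L + ns, ns))
  col <- function(i) vapply(sp, `[[`, character(1), i)
  chrom <- col(1)
  pos <- as.integer(col(2))
  if (anyNA(pos) || any(pos < 1L))
    stop(sprintf("line %d: POS is not a positive integer",
                 line_offset + which(is.na(pos) | pos < 1L)[1]))
  id <- col(3); id[id == "."] <- NA_character_
  ref <- col(4)
  alt <- col(5)
  allele_ok <- grepl("^[ACGTNacgtn]+(,[ACGTNacgtn]+)*$", alt) &
    grepl("^[ACGTNacgtn]+$", ref)
  if (any(!allele_ok))
    stop(sprintf("line %d: non-sequence (symbolic or malformed) allele '%s'",
                 line_offset + which(!allele_ok)[1], alt[which(!allele_ok)[1]]))
  n_alts <- lengths(strsplit(alt, ",", fixed = TRUE))
  qual_s <- col(6)
  qual <- suppressWarnings(as.numeric(qual_s))
  qual[qual_s == "."] <- NA_real_
  filt <- col(7)
  info <- col(8)
  fs <- info_num(info, "FS")
  qd <- info_num(info, "QD")
  dp <- info_num(info, "DP")
  fmt <- strsplit(col(9), ":", fixed = TRUE)
  gt_pos <- vapply(fmt, function(f) match("GT", f), 0L)
  ad_pos <- vapply(fmt, function(f) match("AD", f), 0L)
  if (anyNA(gt_pos))
    stop(sprintf("line %d: FORMAT does not declare GT",
                 line_offset + which(is.na(gt_pos))[1]))

  gt1 <- gt2 <- matrix(NA_integer_, n, ns)
  ad_raw <- matrix(NA_character_, n, ns)
  ref_ad <- alt_ad <- ad_sum <- matrix(NA_integer_, n, ns)
  ad_len <- matrix(0L, n, ns)
  for (j in seq_len(ns)) {
    f <- strsplit(col(9L + j), ":", fixed = TRUE)
    gtj <- mapply(function(x, i) if (!is.na(i) && i <= length(x)) x[[i]]
                  else NA_character_, f, gt_pos, USE.NAMES = FALSE)
    adj <- mapply(function(x, i) if (!is.na(i) && i <= length(x)) x[[i]]
                  else NA_character_, f, ad_pos, USE.NAMES = FALSE)
    g <- parse_gt(gtj)
    gt1[, j] <- g$a
    gt2[, j] <- g$b
    ad_raw[, j] <- adj
    a <- parse_ad(adj, line_offset + seq_len(n))
    ref_ad[, j] <- a$ref
    alt_ad[, j] <- a$alt
    ad_sum[, j] <- a$sum
    ad_len[, j] <- a$len
  }
  # AD length must be 1 + n_alts; otherwise the call is unusable
  ad_mismatch <- ad_len > 0L & ad_len != (n_alts + 1L)
  if (any(ad_mismatch)) {
    rows <- which(rowSums(ad_mismatch) > 0L)
    warning(sprintf(
      "%d record(s) with AD length disagreeing with allele count (first at line %d); affected calls treated as missing",
      length(rows), line_offset + rows[1]), call. = FALSE)
    ref_ad[ad_mismatch] <- NA_integer_
    alt_ad[ad_mismatch] <- NA_integer_
    ad_sum[ad_mismatch] <- NA_integer_
  }
  miss <- is.na(gt1) | is.na(gt2) | is.na(ad_sum)
  dimnames(gt1) <- dimnames(gt2) <- dimnames(ad_raw) <-
    dimnames(ref_ad) <- dimnames(alt_ad) <- dimnames(ad_sum) <-
    dimnames(miss) <- list(NULL, samples)
  structure(list(
    samples = samples,
    sites = data.frame(chrom = chrom, pos = pos, id = id, ref = ref,
                       alt = alt, n_alts = n_alts, qual = qual, filter = filt,
                       fs = fs, qd = qd, dp = dp,
                       line = line_offset + seq_len(n),
                       stringsAsFactors = FALSE),
    gt1 = gt1, gt2 = gt2, ad = ad_raw,
    ref_ad = ref_ad, alt_ad = alt_ad, ad_sum = ad_sum,
    missing = miss), class = "ase_vcf")
}

info_num <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2L)
    suppressWarnings(as.numeric(x[2])) else NA_real_, numeric(1))
}

parse_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(gt, "/", fixed = TRUE)
  a <- rep(NA_integer_, length(gt))
  b <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & lengths(parts) == 2L
  if (any(ok)) {
    a[ok] <- suppressWarnings(as.integer(vapply(parts[ok], `[[`, "", 1L)))
    b[ok] <- suppressWarnings(as.integer(vapply(parts[ok], `[[`, "", 2L)))
  }
  list(a = a, b = b)
}

parse_ad <- function(ad, lines) {
  n <- length(ad)
  out_r <- out_a <- out_s <- rep(NA_integer_, n)
  out_len <- rep(0L, n)
  ok <- !is.na(ad) & ad != "."
  if (any(ok)) {
    parts <- strsplit(ad[ok], ",", fixed = TRUE)
    num_ok <- vapply(parts, function(x) all(grepl("^[0-9]+$", x)), logical(1))
    if (any(!num_ok)) {
      i <- which(ok)[which(!num_ok)[1]]
      stop(sprintf("line %d: non-integer token in AD field '%s'",
                   lines[i], ad[i]))
    }
    vals <- lapply(parts, as.integer)
    idx <- which(ok)
    out_len[idx] <- lengths(vals)
    out_r[idx] <- vapply(vals, `[[`, 0L, 1L)
    out_a[idx] <- vapply(vals, function(x) if (length(x) >= 2L) x[[2L]]
                         else NA_integer_, 0L)
    out_s[idx] <- vapply(vals, sum, 0L)
  }
  list(ref = out_r, alt = out_a, sum = out_s, len = out_len)
}

# Append one parsed chunk to another (same sample set).
rbind_vcf <- function(x, y) {
  stopifnot(identical(x$samples, y$samples))
  structure(list(
    samples = x$samples,
    sites = rbind(x$sites, y$sites),
    gt1 = rbind(x$gt1, y$gt1), gt2 = rbind(x$gt2, y$gt2),
    ad = rbind(x$ad, y$ad),
    ref_ad = rbind(x$ref_ad, y$ref_ad), alt_ad = rbind(x$alt_ad, y$alt_ad),
    ad_sum = rbind(x$ad_sum, y$ad_sum),
    missing = rbind(x$missing, y$missing)), class = "ase_vcf")
}

#' @export
print.ase_vcf <- function(x, ...) {
  cat(sprintf("VCF: %d records, %d samples (%s%s)\n",
              nrow(x$sites), length(x$samples),
              paste(utils::head(x$samples, 4), collapse = ", "),
              if (length(x$samples) > 4) ", ..." else ""))
  invisible(x)
}

#' Parse one genotype call
#'
#' Parses a single sample's GT and AD strings as found in a VCF genotype
#' column. Phasing separators `/` and `|` are equivalent; `./.` or an absent
#' AD field yields a missing call.
#'
#' @param gt_field GT string, e.g. `"0/1"`, `"1|1"`, `"./."`.
#' @param ad_field AD string, e.g. `"10,12"`, or `"."` when absent.
#' @param n_alts Number of ALT alleles at the owning site.
#' @return A list with `gt` (integer pair or NULL), `ad` (integer vector or
#'   NULL) and `missing` (logical).
#' @examples
#' parse_sample_call("0/1", "10,10", 1)
#' parse_sample_call("./.", ".", 1)
#' @export
parse_sample_call <- function(gt_field, ad_field, n_alts) {
  g <- parse_gt(gt_field)
  a <- parse_ad(ad_field, 0L)
  missing <- is.na(g$a) || is.na(g$b) || is.na(a$sum)
  if (!missing && (g$a > n_alts || g$b > n_alts))
    stop(sprintf("GT allele index exceeds allele count (%s with %d ALT)",
                 gt_field, n_alts))
  if (!missing && a$len != n_alts + 1L) missing <- TRUE
  list(
    gt = if (is.na(g$a) || is.na(g$b)) NULL else c(g$a, g$b),
    ad = if (a$len > 0L)
      as.integer(strsplit(ad_field, ",", fixed = TRUE)[[1]]) else NULL,
    missing = missing)
}

#' Write a tabular report
#'
#' Writes a data.frame as a tab-separated file with one header line,
#' deterministic column order, `NA` for missing values and numeric columns
#' rendered at a fixed number of significant digits. A commented provenance
#' line (tool version and caller-supplied parameters) precedes the header;
#' a timestamp is added only on request so that repeated runs are
#' byte-identical.
#'
#' @param rows A data.frame.
#' @param path Output file path.
#' @param digits Significant digits for numeric columns (default 6).
#' @param params Named character/numeric vector echoed into the provenance
#'   comment, or NULL.
#' @param timestamp Add the current time to the provenance line (breaks
#'   byte-reproducibility; default FALSE).
#' @return Invisibly, `path`.
#' @export
write_report <- function(rows, path, digits = 6, params = NULL,
                         timestamp = FALSE) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- signif(out[[j]], digits)
      out[[j]] <- ifelse(is.na(v), NA_character_,
                         format(v, digits = digits, trim = TRUE,
                                scientific = NA))
    }
  }
  prov <- sprintf("# allelic %s%s%s",
                  as.character(utils::packageVersion("allelic")),
                  if (length(params))
                    paste0("; ", paste(names(params), unname(params),
                                       sep = "=", collapse = " ")) else "",
                  if (timestamp) paste0("; ", format(Sys.time())) else "")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(prov, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_report <- function(path) {
  utils::read.delim(path, comment.char = "#", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
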