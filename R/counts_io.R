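#' Construct and validate a pool count table
#'
#' A pool count table holds, for every SNP and every sequenced pool, the
#' number of reads carrying the reference-parent allele (`<pool>_ref`) and
#' the total number of reads (`<pool>_tot`).  Rows are keyed by
#' (`chrom`, `pos`) with 1-based physical coordinates and kept strictly
#' sorted by chromosome then position.  Counts are post quality-filter:
#' any read-level filtering is assumed to have happened upstream.
#'
#' @param df data.frame with columns `chrom`, `pos` and, for each pool,
#'   `<pool>_ref` and `<pool>_tot`.
#' @param pools character vector of pool names; if `NULL`, inferred from
#'   the `_ref`/`_tot` column pairs.
#' @return the validated table, sorted, with class `pool_counts` and a
#'   `pools` attribute.
#' @examples
#' df <- data.frame(chrom = "1", pos = c(100L, 200L),
#'                  high_ref = c(10L, 5L), high_tot = c(20L, 20L),
#'                  low_ref  = c(12L, 9L), low_tot  = c(25L, 18L))
#' pool_counts(df)
#' @export
pool_counts <- function(df, pools = NULL) {
  stopifnot(is.data.frame(df))
  if (!all(c("chrom", "pos") %in% names(df)))
    stop("count table must have 'chrom' and 'pos' columns")
  if (is.null(pools)) {
    refs <- grep("_ref$", names(df), value = TRUE)
    pools <- sub("_ref$", "", refs)
  }
  if (length(pools) == 0L) stop("no pools found in count table")
  if (anyDuplicated(pools)) stop("pool names must be unique")
  need <- c(paste0(pools, "_ref"), paste0(pools, "_tot"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing count columns: ", paste(miss, collapse = ", "))

  df <- df[, c("chrom", "pos", as.vector(rbind(paste0(pools, "_ref"),
                                               paste0(pools, "_tot"))))]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  if (nrow(df) && any(df$pos < 1L, na.rm = TRUE))
    stop("positions must be >= 1 (1-based coordinates)")
  for (cn in need) {
    v <- df[[cn]]
    if (any(is.na(v)) || any(v != as.integer(v)) || any(v < 0))
      stop("column '", cn, "' must contain non-negative integer counts")
    df[[cn]] <- as.integer(v)
  }
  for (p in pools) {
    bad <- which(df[[paste0(p, "_ref")]] > df[[paste0(p, "_tot")]])
    if (length(bad))
      stop("pool '", p, "': ref_count > total_count at row ", bad[1L],
           " (", df$chrom[bad[1L]], ":", df$pos[bad[1L]], ")")
  }
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos): ", key[which(duplicated(key))[1L]])
  df <- df[order(chrom_rank(df$chrom), df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, pools = pools, class = c("pool_counts", "data.frame"))
}

#' Pool names of a count, frequency or scan table
#' @param x an object with a `pools` attribute.
#' @return character vector of pool names.
#' @export
pools <- function(x) attr(x, "pools")

#' Read a per-SNP per-pool allele-count table
#'
#' Reads allele counts in one of three formats and returns a validated,
#' sorted [pool_counts] table:
#'
#' * `tsv` — the canonical interchange dialect: a tab-separated file with
#'   header `chrom pos <pool>_ref <pool>_tot ...`.  This is the only
#'   format [write_counts()] emits, and round-trips exactly.
#' * `vcf_ad` — a VCF whose genotype field carries allelic depths (`AD`);
#'   each named sample becomes a pool with `ref = AD[1]`,
#'   `tot = AD[1] + AD[2]`.  Sites that are not biallelic SNPs are dropped
#'   with a message.  Requires the \pkg{vcfR} package.
#' * `sync` — PoPoolation2 sync records (`chrom pos refbase` then one
#'   `A:T:C:G:N:del` column per pool).  The reference allele is the
#'   `refbase` column; the alternate allele is the most abundant non-
#'   reference base summed over pools.  Sites where more than two bases
#'   are observed are rejected and reported with a message.
#'
#' Plain and gzip-compressed files are both accepted.
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"vcf_ad"`, `"sync"`.
#' @param pool_names for `tsv`, an optional subset of pools to keep; for
#'   `vcf_ad`, a character vector of sample names to import (names give the
#'   pool labels); for `sync`, the names of the count columns in file
#'   order (required).
#' @return a [pool_counts] table.
#' @export
read_counts <- function(path, format = c("tsv", "vcf_ad", "sync"),
                        pool_names = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         tsv = read_counts_tsv(path, pool_names),
         vcf_ad = read_counts_vcf(path, pool_names),
         sync = read_counts_sync(path, pool_names))
}

read_counts_tsv <- function(path, pool_names) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", colClasses = "character",
               check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e)))
  for (cn in setdiff(names(df), "chrom")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) {
      # +1 for the header line
      bad <- which(is.na(v))[1L] + 1L
      stop("malformed value in column '", cn, "' at line ", bad,
           " of ", path)
    }
    df[[cn]] <- v
  }
  if (!is.null(pool_names)) {
    keep <- c("chrom", "pos",
              as.vector(rbind(paste0(pool_names, "_ref"),
                              paste0(pool_names, "_tot"))))
    unknown <- setdiff(keep, names(df))
    if (length(unknown))
      stop("unknown pools requested: ",
           paste(unique(sub("_(ref|tot)$", "", unknown)), collapse = ", "))
    df <- df[, keep]
  }
  pool_counts(df)
}

read_counts_vcf <- function(path, pool_names) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF allelic depths requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad)) stop("VCF has no AD (allelic depth) genotype field")
  samples <- colnames(ad)
  if (is.null(pool_names)) pool_names <- setNames(samples, samples)
  if (is.null(names(pool_names)) || any(!nzchar(names(pool_names))))
    names(pool_names) <- pool_names
  unknown <- setdiff(pool_names, samples)
  if (length(unknown))
    stop("unknown VCF samples requested: ", paste(unknown, collapse = ", "))

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1L & nchar(alt) == 1L
  if (any(!biallelic))
    message(sum(!biallelic),
            " site(s) dropped from VCF: not biallelic SNPs")
  df <- data.frame(chrom = fix[biallelic, "CHROM"],
                   pos = as.integer(fix[biallelic, "POS"]),
                   stringsAsFactors = FALSE)
  for (i in seq_along(pool_names)) {
    x <- ad[biallelic, pool_names[[i]], drop = TRUE]
    parts <- strsplit(ifelse(is.na(x), "0,0", x), ",", fixed = TRUE)
    rc <- vapply(parts, function(p) as.integer(p[1L]), integer(1))
    ac <- vapply(parts, function(p)
      if (length(p) >= 2L) as.integer(p[2L]) else 0L, integer(1))
    rc[is.na(rc)] <- 0L; ac[is.na(ac)] <- 0L
    df[[paste0(names(pool_names)[i], "_ref")]] <- rc
    df[[paste0(names(pool_names)[i], "_tot")]] <- rc + ac
  }
  pool_counts(df, pools = names(pool_names))
}

read_counts_sync <- function(path, pool_names) {
  raw <- tryCatch(
    read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e)))
  n_pools <- ncol(raw) - 3L
  if (n_pools < 1L) stop("sync file must have at least one count column")
  if (is.null(pool_names))
    stop("pool_names (one per sync count column) is required for sync input")
  if (length(pool_names) != n_pools)
    stop("sync file has ", n_pools, " count columns but ",
         length(pool_names), " pool names were given")

  bases <- c("A", "T", "C", "G")
  # counts[[p]] is a 4-column matrix of A/T/C/G counts for pool p
  counts <- lapply(seq_len(n_pools), function(p) {
    parts <- strsplit(raw[[p + 3L]], ":", fixed = TRUE)
    bad <- which(lengths(parts) != 6L)
    if (length(bad))
      stop("malformed sync record at line ", bad[1L], " of ", path)
    m <- matrix(as.integer(unlist(parts)), ncol = 6L, byrow = TRUE)
    m[, 1:4, drop = FALSE]
  })
  total_by_base <- Reduce(`+`, counts)
  refbase <- toupper(raw[[3L]])
  ref_idx <- match(refbase, bases)
  if (anyNA(ref_idx))
    stop("malformed sync record at line ", which(is.na(ref_idx))[1L],
         " of ", path, ": reference base not in A/T/C/G")

  observed <- total_by_base > 0L
  n_alleles <- rowSums(observed)
  multi <- n_alleles > 2L
  if (any(multi))
    message(sum(multi), " sync site(s) rejected: more than two alleles observed")

  # alternate allele: most abundant non-reference base across pools
  tb <- total_by_base
  tb[cbind(seq_len(nrow(tb)), ref_idx)] <- -1L
  alt_idx <- max.col(tb, ties.method = "first")

  keep <- !multi
  df <- data.frame(chrom = as.character(raw[[1L]][keep]),
                   pos = as.integer(raw[[2L]][keep]),
                   stringsAsFactors = FALSE)
  for (p in seq_len(n_pools)) {
    rc <- counts[[p]][cbind(seq_len(nrow(raw)), ref_idx)]
    ac <- counts[[p]][cbind(seq_len(nrow(raw)), alt_idx)]
    df[[paste0(pool_names[p], "_ref")]] <- rc[keep]
    df[[paste0(pool_names[p], "_tot")]] <- (rc + ac)[keep]
  }
  pool_counts(df, pools = pool_names)
}

#' Write a pool count table to the canonical TSV dialect
#'
#' Emits a tab-separated file with header
#' `chrom pos <pool>_ref <pool>_tot ...`.  [read_counts()] on the result
#' reproduces the table exactly.
#'
#' @param table a [pool_counts] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "pool_counts"))
  ok <- tryCatch({
    write.table(table, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}
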