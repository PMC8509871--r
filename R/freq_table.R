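#' Allele-frequency time-series table
#'
#' The universal input container: one row per SNP with genomic coordinates and
#' the focal-allele frequency (optionally read depth) at each of `>= 2` ordered
#' timepoints. Stored as a data frame with columns `chrom`, `pos`,
#' `freq_<label>` and optionally `depth_<label>` for each timepoint label.
#'
#' @param chrom Chromosome identifiers (character).
#' @param pos 1-based positions in bp; strictly increasing within chromosome
#'   after sorting (duplicate positions on a chromosome are an error).
#' @param freq Numeric matrix, loci x timepoints, frequencies in `[0, 1]`
#'   (`NA` allowed for missing measurements, e.g. zero-depth timepoints).
#' @param depth Optional matrix of read depths (`>= 0`), same shape as `freq`.
#' @param t_labels Ordered timepoint labels; defaults to `colnames(freq)` or
#'   `t0, t1, ...`.
#' @param sort Sort loci by chromosome then position (default `TRUE`).
#' @return An object of class `freq_table`.
#' @export
freq_table <- function(chrom, pos, freq, depth = NULL, t_labels = NULL,
                       sort = TRUE) {
  freq <- as.matrix(freq)
  if (is.null(t_labels)) {
    t_labels <- colnames(freq)
    if (is.null(t_labels)) t_labels <- paste0("t", seq_len(ncol(freq)) - 1L)
  }
  x <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  stringsAsFactors = FALSE)
  for (k in seq_along(t_labels)) x[[paste0("freq_", t_labels[k])]] <- freq[, k]
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    for (k in seq_along(t_labels)) {
      x[[paste0("depth_", t_labels[k])]] <- depth[, k]
    }
  }
  if (sort && nrow(x) > 1) {
    x <- x[order(x$chrom, x$pos), , drop = FALSE]
    rownames(x) <- NULL
  }
  validate_freq_table(
    structure(x, t_labels = as.character(t_labels),
              class = c("freq_table", "data.frame")))
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d loci, %d timepoints (%s), %d chromosome(s)\n",
              n_loci(x), length(t_labels(x)),
              paste(t_labels(x), collapse = ", "),
              length(unique(x$chrom))))
  if (has_depth(x)) cat("  read depths present\n")
  nshow <- min(6L, nrow(x))
  if (nshow > 0) print.data.frame(utils::head(as.data.frame(x), nshow))
  invisible(x)
}

#' Timepoint labels of a frequency table
#' @param x A `freq_table`.
#' @return Character vector of ordered timepoint labels.
#' @export
t_labels <- function(x) attr(x, "t_labels")

#' Number of loci in a frequency table
#' @param x A `freq_table`.
#' @return Integer count of rows (loci).
#' @export
n_loci <- function(x) nrow(x)

#' Frequency matrix of a table
#' @param x A `freq_table`.
#' @param labels Timepoint labels to extract (default all, in order).
#' @return Numeric matrix loci x timepoints.
#' @export
freqs <- function(x, labels = t_labels(x)) {
  m <- as.matrix(as.data.frame(x)[paste0("freq_", labels)])
  colnames(m) <- labels
  m
}

#' Depth matrix of a table (or NULL)
#' @param x A `freq_table`.
#' @param labels Timepoint labels to extract.
#' @return Numeric matrix loci x timepoints, or `NULL` when depths absent.
#' @export
depths <- function(x, labels = t_labels(x)) {
  if (!has_depth(x)) return(NULL)
  m <- as.matrix(as.data.frame(x)[paste0("depth_", labels)])
  colnames(m) <- labels
  m
}

has_depth <- function(x) any(startsWith(names(x), "depth_"))

#' Validate a frequency table
#'
#' Checks the container invariants: `>= 2` timepoints, frequencies in `[0, 1]`
#' (or `NA`), nonnegative depths, and strictly increasing positions within each
#' chromosome.
#'
#' @param x A `freq_table`.
#' @return `x` invisibly; stops with an informative error on violation.
#' @export
validate_freq_table <- function(x) {
  stopifnot(inherits(x, "freq_table"))
  lb <- t_labels(x)
  if (length(lb) < 2) stop("freq_table needs >= 2 timepoints")
  f <- freqs(x)
  bad <- which(!is.na(f) & (f < 0 | f > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]
    stop(sprintf("frequency outside [0,1] at locus %s:%s (timepoint %s)",
                 x$chrom[i], format(x$pos[i], scientific = FALSE),
                 lb[bad[1, 2]]))
  }
  d <- depths(x)
  if (!is.null(d) && any(d < 0, na.rm = TRUE)) stop("negative read depth")
  for (ch in unique(x$chrom)) {
    p <- x$pos[x$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop(sprintf("positions not strictly increasing on chromosome %s", ch))
    }
  }
  invisible(x)
}

# Row subset preserving class and attributes; no re-validation (bootstrap
# resamples legitimately repeat loci).
subset_loci <- function(x, idx) {
  y <- as.data.frame(x)[idx, , drop = FALSE]
  rownames(y) <- NULL
  structure(y, t_labels = t_labels(x), class = c("freq_table", "data.frame"))
}

#' Rows with a complete (non-missing) frequency at every timepoint
#' @param x A `freq_table`.
#' @return Logical vector, `TRUE` where all timepoints are observed.
#' @export
complete_loci <- function(x) stats::complete.cases(freqs(x))

#' Read a PoPoolation2-style sync file
#'
#' Parses the standard E&R pool-seq interchange format: tab-separated
#' `chrom pos ref` followed by one `A:T:C:G:N:del` count sextuple per sample
#' column. Only biallelic loci are retained: exactly two of A/T/C/G must have a
#' nonzero count pooled across the selected timepoint columns (N and deletion
#' counts are ignored throughout). The focal allele is the alphabetically first
#' of the two; its frequency is `focal count / (sum of the two allele counts)`
#' and the depth is that sum. A timepoint with zero total depth at a locus
#' yields a missing frequency.
#'
#' @param path Path to the sync file.
#' @param timepoint_columns Ordered indices of the sample columns to use as
#'   timepoints (1 = first column after `ref`); at least 2.
#' @param t_labels Optional labels for the timepoints (default `t0, t1, ...`).
#' @return A `freq_table` with depths. The number of non-biallelic (dropped)
#'   input lines is recorded in attribute `n_dropped`.
#' @export
read_sync <- function(path, timepoint_columns, t_labels = NULL) {
  if (length(timepoint_columns) < 2) {
    stop("configuration error: need >= 2 timepoint columns")
  }
  raw <- if (file.size(path) == 0) {
    data.frame()
  } else {
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = "character", data.table = FALSE)
  }
  if (is.null(t_labels)) {
    t_labels <- paste0("t", seq_along(timepoint_columns) - 1L)
  }
  K <- length(timepoint_columns)
  if (nrow(raw) == 0) {
    warning("empty sync file: ", path)
    tab <- freq_table(character(0), numeric(0),
                      matrix(numeric(0), 0, K),
                      matrix(numeric(0), 0, K), t_labels = t_labels)
    attr(tab, "n_dropped") <- 0L
    return(tab)
  }
  need <- 3 + max(timepoint_columns)
  if (ncol(raw) < need) {
    stop(sprintf("sync file has %d columns; need %d for requested timepoints",
                 ncol(raw), need))
  }
  # counts[locus, timepoint, base] for A,T,C,G
  cnt <- array(NA_real_, dim = c(nrow(raw), K, 4))
  for (k in seq_len(K)) {
    col <- raw[[3 + timepoint_columns[k]]]
    parts <- strsplit(col, ":", fixed = TRUE)
    len <- lengths(parts)
    if (any(len != 6)) {
      stop(sprintf("malformed sextuple at line %d: '%s'",
                   which(len != 6)[1], col[which(len != 6)[1]]))
    }
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 6, byrow = TRUE)
    if (anyNA(m)) {
      stop(sprintf("malformed sextuple at line %d: '%s'",
                   which(rowSums(is.na(m)) > 0)[1],
                   col[which(rowSums(is.na(m)) > 0)[1]]))
    }
    cnt[, k, ] <- m[, 1:4]
  }
  pooled <- apply(cnt, c(1, 3), sum) # locus x base, across timepoints
  n_alleles <- rowSums(pooled > 0)
  keep <- n_alleles == 2
  n_dropped <- sum(!keep)
  bases <- c("A", "T", "C", "G")
  if (sum(keep) == 0) {
    tab <- freq_table(character(0), numeric(0), matrix(numeric(0), 0, K),
                      matrix(numeric(0), 0, K), t_labels = t_labels)
    attr(tab, "n_dropped") <- n_dropped
    return(tab)
  }
  cnt <- cnt[keep, , , drop = FALSE]
  pooled <- pooled[keep, , drop = FALSE]
  # focal = alphabetically first of the two segregating bases
  ord <- order(bases)
  focal_idx <- other_idx <- integer(nrow(pooled))
  for (i in seq_len(nrow(pooled))) {
    seg <- which(pooled[i, ] > 0)
    seg <- seg[order(bases[seg])]
    focal_idx[i] <- seg[1]
    other_idx[i] <- seg[2]
  }
  ii <- seq_len(nrow(pooled))
  fr <- dp <- matrix(NA_real_, nrow(pooled), K)
  for (k in seq_len(K)) {
    fc <- cnt[cbind(ii, k, focal_idx)]
    oc <- cnt[cbind(ii, k, other_idx)]
    tot <- fc + oc
    dp[, k] <- tot
    fr[, k] <- ifelse(tot > 0, fc / tot, NA_real_)
  }
  tab <- freq_table(raw[[1]][keep], as.numeric(raw[[2]][keep]), fr, dp,
                    t_labels = t_labels)
  attr(tab, "n_dropped") <- n_dropped
  validate_freq_table(tab)
  tab
}

#' Read a tab-separated allele-frequency table
#'
#' Expects a header with `chrom`, `pos`, then `freq_<label>` columns (and
#' optional matching `depth_<label>` columns); labels are taken in header
#' order.
#'
#' @param path Path to the TSV file written by [write_freq_table()] or
#'   equivalent.
#' @return A `freq_table`.
#' @export
read_freq_table <- function(path) {
  d <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  if (!all(c("chrom", "pos") %in% names(d))) {
    stop("validation error: table must have 'chrom' and 'pos' columns")
  }
  fcols <- grep("^freq_", names(d), value = TRUE)
  if (length(fcols) < 2) stop("validation error: need >= 2 freq_<label> columns")
  labels <- sub("^freq_", "", fcols)
  dcols <- paste0("depth_", labels)
  depth <- if (all(dcols %in% names(d))) as.matrix(d[dcols]) else NULL
  tab <- freq_table(d$chrom, d$pos, as.matrix(d[fcols]), depth,
                    t_labels = labels, sort = FALSE)
  validate_freq_table(tab)
  tab
}

#' Write a frequency table to TSV
#'
#' Full float precision is preserved (17 significant digits), so
#' `read_freq_table(write_freq_table(x))` reproduces `x` bit-exactly.
#'
#' @param table A `freq_table`.
#' @param path Output path.
#' @return `table`, invisibly.
#' @export
write_freq_table <- function(table, path) {
  stopifnot(inherits(table, "freq_table"))
  d <- as.data.frame(table)
  num <- vapply(d, is.numeric, logical(1)) & names(d) != "pos"
  for (j in which(num)) d[[j]] <- sprintf("%.17g", d[[j]])
  d$pos <- format(d$pos, scientific = FALSE, trim = TRUE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(table)
}
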