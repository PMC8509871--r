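#' Partition loci into genomic blocks
#'
#' Tiles each chromosome with half-open windows `[0, size), [size, 2 size), ...`
#' up to the last locus position; windows containing no loci are dropped. Every
#' locus falls in exactly one block. The default 1 Mb window matches common
#' practice for respecting local linkage in Drosophila-scale genomes.
#'
#' @param table A `freq_table`.
#' @param block_size Window size in bp (default `1e6`).
#' @return A `genomic_blocks` object: data frame with `chrom`, `start`, `end`
#'   plus a list attribute `indices` giving the row indices of `table` in each
#'   block.
#' @export
make_blocks <- function(table, block_size = 1e6) {
  stopifnot(inherits(table, "freq_table"), block_size > 0)
  key <- paste0(table$chrom, "\r", floor(table$pos / block_size))
  idx <- split(seq_len(n_loci(table)), key)
  first <- vapply(idx, `[`, numeric(1), 1)
  ord <- order(table$chrom[first], table$pos[first])
  idx <- idx[ord]
  win <- floor(table$pos[vapply(idx, `[`, numeric(1), 1)] / block_size)
  out <- data.frame(chrom = table$chrom[vapply(idx, `[`, numeric(1), 1)],
                    start = win * block_size, end = (win + 1) * block_size)
  structure(out, indices = unname(idx),
            class = c("genomic_blocks", "data.frame"))
}

#' @export
print.genomic_blocks <- function(x, ...) {
  n <- lengths(attr(x, "indices"))
  cat(sprintf("genomic_blocks: %d blocks on %d chromosome(s); %d loci (%d-%d per block)\n",
              nrow(x), length(unique(x$chrom)), sum(n), min(n), max(n)))
  invisible(x)
}

#' Block-bootstrap confidence interval for a scan statistic
#'
#' Resamples whole genomic blocks with replacement to respect linkage between
#' nearby loci: each bootstrap replicate draws `length(blocks)` blocks,
#' concatenates their loci into a resampled table, and re-evaluates `stat` on
#' it (so binning, variance and any downstream ratio are recomputed per
#' replicate). Confidence bounds are the `alpha/2` and `1 - alpha/2` empirical
#' percentiles over replicates. Replicates on which `stat` errors (e.g. an
#' empty frequency bin) are dropped and counted; more than 20% dropped raises
#' a warning.
#'
#' @param stat Function `freq_table -> numeric` (scalar or fixed-length
#'   vector).
#' @param table A `freq_table`.
#' @param blocks A [make_blocks()] result for `table`.
#' @param B Number of bootstrap replicates (default 1000); `B = 0` computes
#'   the point estimate only.
#' @param alpha Two-sided miscoverage (default 0.05 for 95% intervals).
#' @param seed Root seed; all replicate resampling indices are drawn from it,
#'   so results are deterministic given `seed`.
#' @return A `bootstrap_result` list: `point`, `ci_lo`, `ci_hi`, `B`,
#'   `n_dropped`, `alpha`, `seed`, and the matrix of replicate values
#'   `replicates` (replicates x statistic components).
#' @export
block_bootstrap <- function(stat, table, blocks = make_blocks(table),
                            B = 1000, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(table, "freq_table"), inherits(blocks, "genomic_blocks"),
            B >= 0, alpha > 0, alpha < 1)
  point <- stat(table)
  if (B == 0) {
    return(structure(list(point = point, ci_lo = NULL, ci_hi = NULL, B = 0L,
                          n_dropped = 0L, alpha = alpha, seed = seed,
                          replicates = NULL),
                     class = "bootstrap_result"))
  }
  idx_list <- attr(blocks, "indices")
  nb <- length(idx_list)
  if (!is.null(seed)) set.seed(seed)
  reps <- matrix(NA_real_, B, length(point))
  n_dropped <- 0L
  for (b in seq_len(B)) {
    take <- sample.int(nb, nb, replace = TRUE)
    rt <- subset_loci(table, unlist(idx_list[take], use.names = FALSE))
    val <- tryCatch(stat(rt), error = function(e) NULL)
    # a replicate is dropped when the statistic errors or a component that is
    # defined on the full data comes back undefined (e.g. an emptied bin);
    # components undefined on the full data stay NA throughout
    if (is.null(val) || length(val) != length(point) ||
        any(is.na(val) & !is.na(point))) {
      n_dropped <- n_dropped + 1L
    } else {
      reps[b, ] <- val
    }
  }
  if (n_dropped > 0.2 * B) {
    warning(sprintf("%d of %d bootstrap replicates dropped (stat undefined)",
                    n_dropped, B))
  }
  ok <- rowSums(!is.na(reps)) > 0
  qs <- apply(reps[ok, , drop = FALSE], 2, function(v) {
    if (all(is.na(v))) c(NA_real_, NA_real_)
    else stats::quantile(v, probs = c(alpha / 2, 1 - alpha / 2),
                         names = FALSE, na.rm = TRUE)
  })
  structure(list(point = point, ci_lo = qs[1, ], ci_hi = qs[2, ], B = B,
                 n_dropped = n_dropped, alpha = alpha, seed = seed,
                 replicates = reps[ok, , drop = FALSE]),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  if (is.null(x$ci_lo)) {
    cat(sprintf("point estimate %s (no bootstrap replicates)\n",
                paste(signif(x$point, 4), collapse = ", ")))
  } else {
    for (k in seq_along(x$point)) {
      cat(sprintf("%s%.4g  [%.4g, %.4g]  (%d%% block bootstrap, B = %d%s)\n",
                  if (!is.null(names(x$point))) paste0(names(x$point), ": ") else "",
                  x$point[k], x$ci_lo[k], x$ci_hi[k],
                  round(100 * (1 - x$alpha)), x$B,
                  if (x$n_dropped > 0) sprintf(", %d dropped", x$n_dropped) else ""))
    }
  }
  invisible(x)
}
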