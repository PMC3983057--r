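#' Histogram bin limits used by the SPLASH tags
#'
#' Upper bin limits (inclusive) for the 14 dive-depth bins and 14
#' dive-duration bins programmed into the tags before deployment. Intervals
#' are half-open `(lower, upper]`; the last bin is open-ended. The duration
#' layout includes the 270 s limit that completes the regular 30 s spacing of
#' its neighbourhood.
#'
#' @return numeric vector of 13 finite upper limits plus `Inf`.
#' @export
splash_depth_limits <- function() {
  c(2, 4, 6, 10, 20, 34, 50, 74, 100, 124, 150, 174, 200, Inf)
}

#' @rdname splash_depth_limits
#' @export
splash_duration_limits <- function() {
  c(15, 30, 60, 90, 120, 150, 180, 210, 240, 270, 300, 330, 360, Inf)
}

bin_representatives <- function(limits, open_end_width) {
  lower <- c(0, utils::head(limits, -1))
  mid <- (lower + limits) / 2
  n <- length(limits)
  if (!is.finite(limits[n]))
    mid[n] <- limits[n - 1] + open_end_width / 2
  mid
}

#' Count-weighted mean of a tag histogram
#'
#' Each bin is represented by the midpoint of its half-open interval
#' `(previous limit, limit]`; the open-ended top bin is represented by its
#' lower edge plus `open_end_width / 2`. The mean is the count-weighted mean
#' of these representative values.
#'
#' @param counts non-negative bin counts, same length as `limits`.
#' @param limits inclusive upper bin limits; last may be `Inf`.
#' @param open_end_width assumed width (same units) of the open-ended bin.
#'   Defaults to the width of the last closed bin.
#' @return the mean; `NA_real_` (with a warning) when all counts are zero,
#'   since an empty histogram has no defined mean.
#' @examples
#' cnt <- numeric(14); cnt[6] <- 3
#' histogram_mean(cnt, splash_depth_limits())  # 27: midpoint of (20, 34]
#' @export
histogram_mean <- function(counts, limits,
                           open_end_width = NULL) {
  if (length(counts) != length(limits))
    stop("histogram_mean: counts and limits lengths differ", call. = FALSE)
  if (any(counts < 0)) stop("histogram_mean: negative counts", call. = FALSE)
  if (is.null(open_end_width)) {
    n <- length(limits)
    open_end_width <- if (n >= 3) limits[n - 1] - limits[n - 2] else 0
  }
  tot <- sum(counts)
  if (tot == 0) {
    warning("histogram_mean: all counts zero; mean undefined")
    return(NA_real_)
  }
  sum(counts * bin_representatives(limits, open_end_width)) / tot
}

#' Clean raw 6-h dive records
#'
#' Applies the record-level filtering used before summarisation: duplicate
#' records (same animal, same block start) are dropped keeping the first;
#' for histogram (SPLASH) records, depth bins whose upper edge is at or
#' below 6 m are zeroed (only dives deeper than 6 m are analysed, matching
#' the SRDL onboard dive definition) and the shortest (15 s) duration bin is
#' zeroed (durations above 15 s reduce non-foraging surface behaviour).
#' Records whose block start is not a 6-h UTC boundary
#' (00:00/06:00/12:00/18:00) are rejected and reported.
#'
#' @param blocks data.frame of dive blocks: columns `id`, `block` (POSIXct
#'   UTC), `source` ("SPLASH" or "SRDL"), depth-histogram columns
#'   `d1..d14`, duration-histogram columns `t1..t14` (SPLASH), and/or SRDL
#'   summary columns (`mean_depth`, `sd_depth`, `max_depth`, `mean_dur`,
#'   `sd_dur`, `max_dur`, `n_dives`).
#' @param depth_limits,duration_limits bin limits for the histogram columns.
#' @return the cleaned data.frame, with `n_dives` recomputed from the
#'   surviving histogram counts for SPLASH rows, and an attribute
#'   `"rejected"` holding any malformed rows.
#' @export
clean_records <- function(blocks,
                          depth_limits = splash_depth_limits(),
                          duration_limits = splash_duration_limits()) {
  if (nrow(blocks) == 0) {
    attr(blocks, "rejected") <- blocks
    return(blocks)
  }
  stopifnot(all(c("id", "block", "source") %in% names(blocks)))
  blocks$block <- as.POSIXct(blocks$block, tz = "UTC")

  on_boundary <- as.numeric(blocks$block) %% (6 * 3600) == 0
  rejected <- blocks[!on_boundary, , drop = FALSE]
  if (nrow(rejected))
    warning(sprintf("clean_records: %d record(s) not on a 6-h boundary rejected",
                    nrow(rejected)))
  blocks <- blocks[on_boundary, , drop = FALSE]

  dup <- duplicated(blocks[, c("id", "block")])
  blocks <- blocks[!dup, , drop = FALSE]

  dcols <- paste0("d", seq_along(depth_limits))
  tcols <- paste0("t", seq_along(duration_limits))
  is_splash <- blocks$source == "SPLASH"
  if (any(is_splash) && all(dcols %in% names(blocks))) {
    zero_d <- dcols[depth_limits <= 6]
    blocks[is_splash, zero_d] <- 0
    if (all(tcols %in% names(blocks))) {
      zero_t <- tcols[c(TRUE, rep(FALSE, length(duration_limits) - 1))]
      blocks[is_splash, zero_t] <- 0
    }
    if (!"n_dives" %in% names(blocks)) blocks$n_dives <- NA_real_
    blocks$n_dives[is_splash] <-
      rowSums(blocks[is_splash, dcols, drop = FALSE])
  }
  rownames(blocks) <- NULL
  attr(blocks, "rejected") <- rejected
  blocks
}

#' Summarise cleaned dive blocks into per-block depth/duration means
#'
#' For SPLASH rows the means come from [histogram_mean()]; SRDL rows carry
#' their onboard-computed summaries through unchanged.
#'
#' @param blocks a cleaned data.frame from [clean_records()].
#' @inheritParams clean_records
#' @return data.frame `id`, `block`, `source`, `n_dives`, `mean_depth`,
#'   `mean_dur` (plus `max_depth`/`max_dur` where available). Blocks with no
#'   analysable dives get `NA` means.
#' @export
summarize_dive_blocks <- function(blocks,
                                  depth_limits = splash_depth_limits(),
                                  duration_limits = splash_duration_limits()) {
  dcols <- paste0("d", seq_along(depth_limits))
  tcols <- paste0("t", seq_along(duration_limits))
  out <- data.frame(id = blocks$id, block = blocks$block,
                    source = blocks$source,
                    n_dives = if ("n_dives" %in% names(blocks))
                      blocks$n_dives else NA_real_,
                    mean_depth = NA_real_, mean_dur = NA_real_,
                    max_depth = NA_real_, max_dur = NA_real_)
  for (i in seq_len(nrow(blocks))) {
    if (blocks$source[i] == "SPLASH" && all(dcols %in% names(blocks))) {
      cnt <- as.numeric(blocks[i, dcols])
      if (sum(cnt) > 0)
        out$mean_depth[i] <- histogram_mean(cnt, depth_limits)
      if (all(tcols %in% names(blocks))) {
        tc <- as.numeric(blocks[i, tcols])
        if (sum(tc) > 0)
          out$mean_dur[i] <- histogram_mean(tc, duration_limits)
      }
    } else {
      for (col in c("mean_depth", "mean_dur", "max_depth", "max_dur"))
        if (col %in% names(blocks)) out[[col]][i] <- blocks[[col]][i]
    }
  }
  out
}
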