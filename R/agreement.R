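#' Consensus rating per item from multiple ordinal raters
#'
#' The consensus is the modal (most common) non-missing rating per item. Ties
#' are broken toward the higher severity -- a screening-oriented rule that
#' favours sensitivity. The derived binary bradykinesia flag is consensus
#' rating >= 1 on the 0-4 finger-tapping scale.
#'
#' @param ratings Long tibble: `item_id`, `rater_id`, `rating` (0-4 integer
#'   or NA).
#' @return Tibble: `item_id`, `consensus`, `bradykinesia` (logical).
#' @examples
#' r <- tibble::tibble(item_id = rep("v1", 4), rater_id = paste0("r", 1:4),
#'                     rating = c(1, 1, 2, 2))
#' consensus_labels(r)  # tie 1 vs 2 -> 2
#' @export
consensus_labels <- function(ratings) {
  stopifnot(all(c("item_id", "rater_id", "rating") %in% names(ratings)))
  r <- dplyr::filter(ratings, !is.na(.data$rating))
  if (!nrow(r) || length(setdiff(unique(ratings$item_id), unique(r$item_id)))) {
    stop("item(s) with no non-missing rating")
  }
  out <- dplyr::summarise(
    dplyr::group_by(r, .data$item_id),
    consensus = majority_label(.data$rating), .groups = "drop"
  )
  out$bradykinesia <- out$consensus >= 1
  dplyr::arrange(out, .data$item_id)
}

#' Modal rating with higher-severity tie-break
#'
#' @param x Vector of ratings for one item (at least one non-missing value).
#' @return The most common rating; among equally common ratings, the highest.
#' @examples
#' majority_label(c(1, 1, 2, 3))  # 1
#' majority_label(c(1, 1, 2, 2))  # 2
#' @export
majority_label <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("all ratings missing")
  tab <- table(x)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  max(modes)
}

# items x raters matrix from a long ratings table
ratings_matrix <- function(ratings) {
  if (is.matrix(ratings)) return(ratings)
  stopifnot(all(c("item_id", "rater_id", "rating") %in% names(ratings)))
  wide <- tidyr::pivot_wider(
    dplyr::select(ratings, "item_id", "rater_id", "rating"),
    names_from = "rater_id", values_from = "rating"
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- as.character(wide$item_id)
  m
}

#' Krippendorff's alpha inter-rater agreement
#'
#' Chance-corrected agreement for any number of raters with missing entries
#' allowed: alpha = 1 - D_o / D_e, computed from the coincidence matrix of
#' pairable values within items. Items with fewer than two ratings are
#' ignored (they contribute no pairs). The `nominal` metric scores any
#' disagreement 1; the `ordinal` metric uses the squared cumulative-margin
#' distance appropriate for graded 0-4 severity ratings.
#'
#' @param ratings Long tibble (`item_id`, `rater_id`, `rating`) or an items x
#'   raters matrix with NAs for missing ratings.
#' @param level Metric level: `"ordinal"` (default, for 0-4 scores) or
#'   `"nominal"`.
#' @return Alpha in [-1, 1].
#' @examples
#' m <- rbind(c(1, 1), c(2, 2), c(3, 3), c(3, 4))
#' krippendorff_alpha(m, level = "nominal")
#' @export
krippendorff_alpha <- function(ratings, level = c("ordinal", "nominal")) {
  level <- match.arg(level)
  m <- ratings_matrix(ratings)
  m <- m[rowSums(!is.na(m)) >= 2, , drop = FALSE]
  if (nrow(m) < 1) stop("need at least one item with two or more ratings")

  vals <- sort(unique(as.vector(m[!is.na(m)])))
  q <- length(vals)
  # coincidence matrix: within-item ordered pairs weighted by 1/(m_u - 1)
  co <- matrix(0, q, q, dimnames = list(vals, vals))
  for (u in seq_len(nrow(m))) {
    r <- m[u, ][!is.na(m[u, ])]
    mu <- length(r)
    ci <- match(r, vals)
    for (a in seq_len(mu)) {
      for (b in seq_len(mu)) {
        if (a != b) co[ci[a], ci[b]] <- co[ci[a], ci[b]] + 1 / (mu - 1)
      }
    }
  }
  nc <- rowSums(co)
  n <- sum(nc)
  delta2 <- matrix(0, q, q)
  for (c1 in seq_len(q)) {
    for (c2 in seq_len(q)) {
      if (c1 == c2) next
      delta2[c1, c2] <- if (level == "nominal") 1 else {
        lo <- min(c1, c2); hi <- max(c1, c2)
        (sum(nc[lo:hi]) - (nc[c1] + nc[c2]) / 2)^2
      }
    }
  }
  d_e <- sum(outer(nc, nc) * delta2)
  if (d_e == 0) {
    stop("alpha undefined: zero expected disagreement (single rating value)")
  }
  d_o <- sum(co * delta2)
  1 - (n - 1) * d_o / d_e
}

#' Bootstrap confidence interval for Krippendorff's alpha
#'
#' Percentile interval from resampling items (subjects) with replacement.
#' Replicates on which alpha is undefined (e.g. a resample with a single
#' rating value) are skipped and counted; a warning is raised if more than 5%
#' are skipped.
#'
#' @inheritParams krippendorff_alpha
#' @param iterations Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Tibble: `alpha`, `ci_low`, `ci_high`, `iterations`, `skipped`.
#' @export
alpha_bootstrap_ci <- function(ratings, level = c("ordinal", "nominal"),
                               iterations = 1000, seed = 1, conf = 0.95) {
  level <- match.arg(level)
  m <- ratings_matrix(ratings)
  point <- krippendorff_alpha(m, level = level)
  set.seed(seed)
  reps <- numeric(0)
  skipped <- 0L
  for (i in seq_len(iterations)) {
    mi <- m[sample.int(nrow(m), nrow(m), replace = TRUE), , drop = FALSE]
    a <- tryCatch(krippendorff_alpha(mi, level = level), error = function(e) NA)
    if (is.na(a)) skipped <- skipped + 1L else reps <- c(reps, a)
  }
  if (skipped > 0.05 * iterations) {
    warning(skipped, " of ", iterations,
            " bootstrap replicates had undefined alpha")
  }
  ci <- quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  tibble::tibble(alpha = point, ci_low = ci[1], ci_high = ci[2],
                 iterations = iterations, skipped = skipped)
}
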