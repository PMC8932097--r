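#' Classify eight-item food-insecurity responses
#'
#' The eight experience-scale items are ordered from least to most
#' severe: (1) worried about food, (2) unable to eat healthy food,
#' (3) ate few kinds of foods, (4) skipped a meal, (5) ate less than
#' thought, (6) household ran out of food, (7) hungry but did not eat,
#' (8) went a whole day without eating.
#'
#' Two classification dialects are supported:
#' \describe{
#'   \item{`"item"`}{moderate-to-severe = any of items 4-8 affirmed;
#'     severe = item 7 or 8 affirmed (the default).}
#'   \item{`"rawscore"`}{moderate-to-severe = at least 4 of 8 items
#'     affirmed; severe = at least 7. On responses with a Guttman
#'     structure (affirming a harder item implies affirming all easier
#'     ones) the two dialects coincide.}
#' }
#'
#' @param responses data frame (or matrix) with binary columns
#'   `q1`..`q8` (0/1/NA).
#' @param dialect `"item"` or `"rawscore"`.
#' @return data frame with logical columns `msfi` and `sfi`. Rows with
#'   any missing classification-relevant item get `NA` flags (the
#'   caller's missing-data policy applies; [weighted_prevalence()]
#'   drops and counts them).
#' @export
classify_responses <- function(responses, dialect = c("item", "rawscore")) {
  dialect <- match.arg(dialect)
  qcols <- paste0("q", 1:8)
  if (!all(qcols %in% colnames(responses))) {
    stop("responses must have columns q1..q8")
  }
  q <- as.matrix(as.data.frame(responses)[, qcols])
  storage.mode(q) <- "integer"
  if (any(q[!is.na(q)] != 0L & q[!is.na(q)] != 1L)) {
    stop("item answers must be 0, 1, or missing")
  }
  if (dialect == "item") {
    msfi <- rowSums(q[, 4:8, drop = FALSE]) > 0L
    sfi <- rowSums(q[, 7:8, drop = FALSE]) > 0L
    # an affirmed item settles the flag even when another item is missing
    msfi[is.na(msfi)] <- ifelse(rowSums(q[, 4:8, drop = FALSE], na.rm = TRUE)[is.na(msfi)] > 0, TRUE, NA)
    sfi[is.na(sfi)] <- ifelse(rowSums(q[, 7:8, drop = FALSE], na.rm = TRUE)[is.na(sfi)] > 0, TRUE, NA)
  } else {
    score <- rowSums(q)
    msfi <- score >= 4L
    sfi <- score >= 7L
  }
  # severe implies moderate-to-severe by construction in both dialects
  data.frame(msfi = msfi, sfi = sfi)
}

#' Survey-weighted prevalence of a binary flag
#'
#' prevalence = 100 * sum(w * flag) / sum(w), invariant to uniform
#' rescaling of the weights. Records with missing flags are dropped and
#' counted.
#'
#' @param flag logical vector.
#' @param weight positive survey weights, same length.
#' @return list with `prevalence` (percent), `n` (respondents used),
#'   `effective_n` (Kish effective sample size, (sum w)^2 / sum w^2),
#'   and `n_dropped`.
#' @export
weighted_prevalence <- function(flag, weight) {
  if (length(flag) != length(weight)) stop("flag and weight lengths differ")
  if (any(weight <= 0, na.rm = TRUE)) stop("survey weights must be positive")
  keep <- !is.na(flag) & !is.na(weight)
  n_dropped <- sum(!keep)
  flag <- flag[keep]
  weight <- weight[keep]
  if (length(flag) == 0L) stop("no valid respondents")
  sw <- sum(weight)
  if (sw <= 0) stop("total survey weight is zero")
  list(
    prevalence = 100 * sum(weight * flag) / sw,
    n = length(flag),
    effective_n = sw^2 / sum(weight^2),
    n_dropped = n_dropped
  )
}

#' Region-year prevalence table from individual responses
#'
#' Classifies every respondent with [classify_responses()] and
#' aggregates to weighted prevalences per region-year.
#'
#' @param responses data frame with `region_id`, `year`, `weight`,
#'   `q1`..`q8`.
#' @inheritParams classify_responses
#' @return data frame `region_id`, `year`, `msfi`, `sfi` (percent),
#'   `n_respondents`, `effective_n`, `n_dropped`; `sfi <= msfi` on every
#'   row.
#' @export
prevalence_by_region_year <- function(responses, dialect = c("item", "rawscore")) {
  dialect <- match.arg(dialect)
  need <- c("region_id", "year", "weight", paste0("q", 1:8))
  miss <- setdiff(need, names(responses))
  if (length(miss) > 0L) stop("responses missing column(s): ", paste(miss, collapse = ", "))
  if (any(responses$weight <= 0, na.rm = TRUE)) stop("survey weights must be positive")
  flags <- classify_responses(responses, dialect)
  key <- interaction(responses$region_id, responses$year, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    i <- key == k
    pm <- weighted_prevalence(flags$msfi[i], responses$weight[i])
    ps <- weighted_prevalence(flags$sfi[i], responses$weight[i])
    data.frame(
      region_id = as.character(responses$region_id[i][1L]),
      year = responses$year[i][1L],
      msfi = pm$prevalence, sfi = ps$prevalence,
      n_respondents = pm$n, effective_n = pm$effective_n,
      n_dropped = pm$n_dropped
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$region_id, out$year), ]
  rownames(out) <- NULL
  out
}
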