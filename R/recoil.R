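#' Inter-edge distance trajectory of an ablated junction
#'
#' Euclidean distance between the two tracked cut edges at each frame.
#'
#' @param track Data frame with columns `time_s`, `e1x_um`, `e1y_um`,
#'   `e2x_um`, `e2y_um` and an `ablation_time_s` attribute or column.
#' @return The track as a tibble with a `distance_um` column.
#' @export
edge_distance <- function(track) {
  cols <- c("time_s", "e1x_um", "e1y_um", "e2x_um", "e2y_um")
  stopifnot(is.data.frame(track), all(cols %in% names(track)))
  if (!all(vapply(track[cols], function(x) all(is.finite(x)), logical(1)))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  out <- tibble::as_tibble(track)
  out$distance_um <- sqrt((track$e1x_um - track$e2x_um)^2 +
                            (track$e1y_um - track$e2y_um)^2)
  out
}

ablation_time <- function(track, ablation_time_s = NULL) {
  ablation_time_s %||% attr(track, "ablation_time_s") %||%
    (if ("ablation_time_s" %in% names(track)) track$ablation_time_s[1] else 0)
}

#' Initial recoil rate over the first 2 s after ablation
#'
#' One-sided secant of the inter-edge distance over the first 2 s
#' post-ablation: `(d(t_a + 2) - d(t_a)) / 2`, with `t_a` the first frame
#' at or after the ablation time. Frames are matched within half a frame
#' interval.
#'
#' @inheritParams edge_distance
#' @param ablation_time_s Time of the cut; defaults to the track's
#'   attribute/column, else 0.
#' @param interval_s Secant interval (2 s, one frame at the standard
#'   acquisition rate).
#' @return One-row tibble: `t_ablation_s`, `initial_rate_um_s`.
#' @export
initial_recoil <- function(track, ablation_time_s = NULL, interval_s = 2) {
  d <- edge_distance(track)
  t_a <- ablation_time(track, ablation_time_s)
  dt <- stats::median(diff(d$time_s))
  i0 <- which(d$time_s >= t_a - dt / 2)[1]
  if (is.na(i0)) stop("no frame at or after ablation", call. = FALSE)
  t0 <- d$time_s[i0]
  i1 <- which(abs(d$time_s - (t0 + interval_s)) <= dt / 2)[1]
  if (is.na(i1)) {
    stop("no frame within half an interval of ", t0 + interval_s,
         " s (gap after ablation)", call. = FALSE)
  }
  rate <- (d$distance_um[i1] - d$distance_um[i0]) /
    (d$time_s[i1] - d$time_s[i0])
  tibble::tibble(t_ablation_s = t0, initial_rate_um_s = rate)
}

#' Compare initial recoil rates across conditions
#'
#' One-way ANOVA on the initial recoil rates plus all pairwise comparisons
#' with Sidak correction (each pairwise Welch p-value `p` adjusted to
#' `1 - (1 - p)^m` over the `m` comparisons).
#'
#' @param rates Data frame with columns `condition`, `initial_rate_um_s`.
#' @return List with `summary` (per-condition mean/SD/sem/n), `anova`
#'   (F, p), and `pairwise` (tibble of Sidak-adjusted pairwise p-values).
#' @export
compare_recoil <- function(rates) {
  stopifnot(all(c("condition", "initial_rate_um_s") %in% names(rates)))
  counts <- table(rates$condition)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need >= 2 conditions with >= 2 tracks each", call. = FALSE)
  }
  summ <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(rates), .data$condition),
    n = dplyr::n(),
    mean_rate = mean(.data$initial_rate_um_s),
    sd_rate = stats::sd(.data$initial_rate_um_s),
    sem_rate = .data$sd_rate / sqrt(.data$n),
    .groups = "drop")
  a <- stats::anova(stats::aov(rates$initial_rate_um_s ~ factor(rates$condition)))
  conds <- names(counts)
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  m <- length(pairs)
  pw <- purrr::map_dfr(pairs, function(pr) {
    x <- rates$initial_rate_um_s[rates$condition == pr[1]]
    y <- rates$initial_rate_um_s[rates$condition == pr[2]]
    p_raw <- stats::t.test(x, y)$p.value
    tibble::tibble(group1 = pr[1], group2 = pr[2], p_raw = p_raw,
                   p_sidak = 1 - (1 - p_raw)^m)
  })
  list(summary = summ,
       anova = tibble::tibble(F = a$`F value`[1], p.value = a$`Pr(>F)`[1]),
       pairwise = pw)
}

#' Mean recoil trajectory with s.e.m. per frame
#'
#' @param tracks List of edge tracks (all sharing frame times) or a data
#'   frame with a `track_id` column.
#' @return Tibble per frame: `time_s`, `n`, `mean_distance_um`, `sem_um`.
#' @export
recoil_trajectory <- function(tracks) {
  if (is.data.frame(tracks)) {
    tracks <- split(tracks[setdiff(names(tracks), "track_id")], tracks$track_id)
  }
  d <- purrr::imap_dfr(tracks, function(tr, id) {
    dd <- edge_distance(tr)
    tibble::tibble(track_id = as.character(id), time_s = dd$time_s,
                   distance_um = dd$distance_um)
  })
  dplyr::summarise(
    dplyr::group_by(d, .data$time_s),
    n = dplyr::n(),
    mean_distance_um = mean(.data$distance_um),
    sem_um = stats::sd(.data$distance_um) / sqrt(dplyr::n()),
    .groups = "drop")
}
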