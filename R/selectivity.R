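# Selectivity index over the two cuff pairs and its optimization.

#' Selectivity counts from two response sets
#'
#' Set algebra over responding channels: T_12 and T_34 are the channels
#' responding to each cuff pair, T_S the channels responding to both, and
#' T_R the channels responding to either, so T_12 + T_34 - T_S = T_R.
#'
#' @param resp12,resp34 [response_set()] objects for cuff pairs 1:2 and 3:4.
#' @param n_channels Total number of MEA channels (32).
#' @return An object of class `selectivity_counts` with fields `t12`, `t34`,
#'   `ts`, `tr`, `n_channels` and the underlying channel sets.
#' @export
count_responses <- function(resp12, resp34, n_channels = 32L) {
  s12 <- responding_channels(resp12)
  s34 <- responding_channels(resp34)
  if (any(c(s12, s34) > n_channels))
    stop("channel index exceeds n_channels = ", n_channels)
  selectivity_counts(length(s12), length(s34), length(intersect(s12, s34)),
                     n_channels, channels_12 = s12, channels_34 = s34)
}

#' Construct validated selectivity counts
#'
#' @param t12,t34 Channels responding to pair 1:2 / 3:4.
#' @param ts Channels responding to both pairs.
#' @param n_channels Total MEA channels.
#' @param channels_12,channels_34 Optional underlying channel sets.
#' @return An object of class `selectivity_counts`.
#' @export
selectivity_counts <- function(t12, t34, ts, n_channels = 32L,
                               channels_12 = NULL, channels_34 = NULL) {
  tr <- t12 + t34 - ts
  if (ts < 0 || ts > min(t12, t34))
    stop("invalid counts: need 0 <= T_S <= min(T_12, T_34)")
  if (tr > n_channels)
    stop("invalid counts: T_R exceeds n_channels")
  structure(list(t12 = as.integer(t12), t34 = as.integer(t34),
                 ts = as.integer(ts), tr = as.integer(tr),
                 n_channels = as.integer(n_channels),
                 channels_12 = channels_12, channels_34 = channels_34),
            class = "selectivity_counts")
}

#' Selectivity index
#'
#' SI = 0.5 (T_R - T_S) / n + 0.5 (1 - |T_12 - T_34| / T_R), with n the
#' number of MEA channels (32). The first term rewards many channels driven
#' by exactly one cuff pair; the second penalizes imbalance between the
#' pairs. SI lies in \[0, 1\], reaching 1 only for balanced, fully selective
#' recruitment of the whole array. With no responses at all (T_R = 0) the
#' balance term is 0/0; SI is defined as 0 (no responses means no
#' selectivity).
#'
#' @param counts A [selectivity_counts()].
#' @return SI in \[0, 1\].
#' @export
selectivity_index <- function(counts) {
  stopifnot(inherits(counts, "selectivity_counts"))
  if (counts$tr == 0) return(0)
  0.5 * (counts$tr - counts$ts) / counts$n_channels +
    0.5 * (1 - abs(counts$t12 - counts$t34) / counts$tr)
}

#' Optimize the selectivity index over tested amplitude pairs
#'
#' Exhaustively evaluates SI over the Cartesian product of the amplitudes
#' tested for the two cuff pairs, excluding combinations with more than
#' `overlap_limit` overlapping channels (more than ~10 percent of the array
#' would not be functionally useful). Ties are broken toward the lowest
#' summed amplitude, then the lowest pair-1:2 amplitude (less injected
#' charge). If every combination is excluded the result is flagged
#' infeasible.
#'
#' @param grid12,grid34 Named lists mapping tested amplitude (as names, uA)
#'   to the [response_set()] evoked through pair 1:2 / 3:4.
#' @param overlap_limit Largest tolerated T_S (default 3).
#' @param n_channels Total MEA channels.
#' @return An object of class `selectivity_result`: list with `feasible`,
#'   `si`, `amplitude_pair` (uA for 1:2 and 3:4), `counts`, selective channel
#'   sets per pair, and `table` (all evaluated combinations).
#' @export
optimize_selectivity <- function(grid12, grid34, overlap_limit = 3,
                                 n_channels = 32L) {
  if (length(grid12) == 0 || length(grid34) == 0)
    stop("empty amplitude grid")
  a12 <- as.numeric(names(grid12))
  a34 <- as.numeric(names(grid34))
  combos <- expand.grid(i = seq_along(a12), j = seq_along(a34))
  ev <- lapply(seq_len(nrow(combos)), function(r) {
    cnt <- count_responses(grid12[[combos$i[r]]], grid34[[combos$j[r]]],
                           n_channels)
    data.frame(i = combos$i[r], j = combos$j[r],
               amp_12 = a12[combos$i[r]], amp_34 = a34[combos$j[r]],
               t12 = cnt$t12, t34 = cnt$t34, ts = cnt$ts, tr = cnt$tr,
               si = selectivity_index(cnt))
  })
  tab <- do.call(rbind, ev)
  tab$feasible <- tab$ts <= overlap_limit
  if (!any(tab$feasible)) {
    return(structure(list(feasible = FALSE, si = NA_real_,
                          amplitude_pair = c(NA_real_, NA_real_),
                          counts = NULL, table = tab),
                     class = "selectivity_result"))
  }
  cand <- tab[tab$feasible, ]
  cand <- cand[order(-cand$si, cand$amp_12 + cand$amp_34, cand$amp_12), ]
  best <- cand[1, ]
  r12 <- grid12[[best$i]]
  r34 <- grid34[[best$j]]
  cnt <- count_responses(r12, r34, n_channels)
  structure(list(
    feasible = TRUE, si = best$si,
    amplitude_pair = c(`1:2` = best$amp_12, `3:4` = best$amp_34),
    counts = cnt,
    selective_12 = setdiff(cnt$channels_12, cnt$channels_34),
    selective_34 = setdiff(cnt$channels_34, cnt$channels_12),
    response_sets = list(`1:2` = r12, `3:4` = r34),
    table = tab), class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  if (!x$feasible) cat("Selectivity: no feasible amplitude combination\n")
  else cat(sprintf(
    "Selectivity: SI = %.3f at %g uA (1:2) / %g uA (3:4); T12=%d T34=%d TS=%d\n",
    x$si, x$amplitude_pair[1], x$amplitude_pair[2],
    x$counts$t12, x$counts$t34, x$counts$ts))
  invisible(x)
}

#' Selectively responding channels per cuff pair
#'
#' Counts the channels each pair recruits selectively. With `allowance = 0`
#' shared channels are excluded from both pairs; with a positive allowance
#' (protocol: 3 channels, ~10 percent of the array) shared channels are
#' included provided the total overlap does not exceed the allowance.
#'
#' @param resp12,resp34 [response_set()] objects.
#' @param allowance Number of tolerated overlapping channels (0 or 3).
#' @return Named integer vector with counts for `"1:2"` and `"3:4"`.
#' @export
selective_channel_summary <- function(resp12, resp34, allowance = 0) {
  s12 <- responding_channels(resp12)
  s34 <- responding_channels(resp34)
  shared <- intersect(s12, s34)
  if (length(shared) <= allowance)
    c(`1:2` = length(s12), `3:4` = length(s34))
  else
    c(`1:2` = length(setdiff(s12, s34)), `3:4` = length(setdiff(s34, s12)))
}
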