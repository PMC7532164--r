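#' @name trajectory-builder
#' @title Step two: linear disease trajectories
#'
#' @description Significant directional pairs are concatenated end-to-end:
#' if D1 -> D2 and D2 -> D3 are both directional pairs they fuse into the
#' length-3 trajectory D1 -> D2 -> D3, and so on up to length 6. A patient
#' *follows* a trajectory when the first occurrences of all its codes exist
#' and are strictly increasing in trajectory order; other intervening
#' diagnoses are irrelevant. Only trajectories followed by at least
#' `min_followers` patients (default 20) are reported, at every length: a
#' retained length-3 trajectory does not suppress its length-2 prefixes.
#' A direct pair D1 -> D3 is never synthesised from D1 -> D2 -> D3.
NULL

## wide first-occurrence date matrix restricted to `codes` (patients x codes)
follower_date_matrix <- function(reg, codes) {
  fo <- first_occurrences(reg)[code %in% codes]
  if (!nrow(fo)) return(NULL)
  w <- data.table::dcast(fo, patient_id ~ code, value.var = "first_date")
  miss <- setdiff(codes, names(w))
  for (mcol in miss) w[, (mcol) := as.Date(NA)]
  w
}

follower_ids <- function(reg, codes) {
  stopifnot(length(codes) >= 2L, !anyDuplicated(codes))
  w <- follower_date_matrix(reg, codes)
  if (is.null(w)) return(character(0))
  d <- do.call(cbind, lapply(w[, codes, with = FALSE], as.numeric))
  ok <- rowSums(is.na(d)) == 0L
  if (length(codes) > 1L)
    for (j in seq_len(length(codes) - 1L))
      ok <- ok & !is.na(d[, j]) & !is.na(d[, j + 1L]) & d[, j] < d[, j + 1L]
  w$patient_id[which(ok)]
}

#' Count patients following an ordered code sequence
#'
#' A patient follows `codes` when their first occurrence of every code in
#' the list exists and the first-occurrence dates are strictly increasing in
#' list order ("without skipping": equal dates break the chain; diagnoses
#' not in the list may occur in between).
#'
#' @param reg a `registry`.
#' @param codes ordered character vector of at least two distinct codes.
#' @return the follower count.
#' @export
count_followers <- function(reg, codes) {
  length(follower_ids(reg, codes))
}

#' Build linear trajectories from directional pairs
#'
#' Depth-first concatenation of directional pairs into chains of length 2 to
#' `max_length`. A chain is retained when its follower count (see
#' [count_followers()]) reaches `min_followers`; since followers of an
#' extension are a subset of followers of its prefix, search is pruned as
#' soon as a chain drops below the threshold. Codes never repeat within one
#' trajectory and the death code can only sit at the end. All qualifying
#' lengths are reported.
#'
#' @param pairs a `directional_pairs` object from
#'   [mine_directional_pairs()], or a data.frame with columns `d1`, `d2`
#'   (extra columns are carried into the edge statistics).
#' @param reg the `registry` used for follower counting (death events are
#'   injected automatically when any pair involves the death code).
#' @param min_followers minimum patients following a reported trajectory.
#' @param max_length maximum trajectory length (codes), default 6.
#' @return a `trajectory_set`: `data.table` with columns `trajectory`
#'   ("A->B->C"), `codes` (list column), `length` and `n_followers`, sorted
#'   lexicographically; the pair table is attached as attribute `pairs`.
#' @export
build_trajectories <- function(pairs, reg, min_followers = 20L,
                               max_length = 6L) {
  pair_dt <- if (inherits(pairs, "directional_pairs"))
    pairs$pairs else data.table::as.data.table(pairs)
  stopifnot(inherits(reg, "registry"), max_length >= 2L, min_followers >= 0L)
  empty <- data.table::data.table(trajectory = character(),
                                  codes = list(), length = integer(),
                                  n_followers = integer())
  if (!nrow(pair_dt)) return(as_trajectory_set(empty, pair_dt))
  if (anyDuplicated(pair_dt[, .(d1, d2)]))
    stop("duplicate pairs in input", call. = FALSE)
  if (nrow(merge(pair_dt[, .(d1, d2)],
                 pair_dt[, .(d1 = d2, d2 = d1)], by = c("d1", "d2"))))
    stop("input contains a pair and its reverse", call. = FALSE)
  if (DEATH_CODE %in% pair_dt$d1)
    stop("death code cannot start a pair", call. = FALSE)
  if (any(c(pair_dt$d1, pair_dt$d2) == DEATH_CODE) &&
      !(DEATH_CODE %in% reg$events$code))
    reg <- inject_death_events(reg)
  adj <- split(pair_dt$d2, pair_dt$d1)
  out_codes <- list(); out_n <- integer(0)
  extend <- function(chain, n_chain) {
    out_codes[[length(out_codes) + 1L]] <<- chain
    out_n[[length(out_n) + 1L]] <<- n_chain
    if (length(chain) >= max_length) return()
    nexts <- adj[[chain[length(chain)]]]
    for (nx in setdiff(nexts, chain)) {
      cand <- c(chain, nx)
      n_cand <- count_followers(reg, cand)
      if (n_cand >= min_followers) extend(cand, n_cand)
    }
  }
  for (i in seq_len(nrow(pair_dt))) {
    chain <- c(pair_dt$d1[i], pair_dt$d2[i])
    n2 <- count_followers(reg, chain)
    if (n2 >= min_followers) extend(chain, n2)
  }
  if (!length(out_codes)) return(as_trajectory_set(empty, pair_dt))
  res <- data.table::data.table(
    trajectory = vapply(out_codes, paste, "", collapse = "->"),
    codes = out_codes,
    length = lengths(out_codes),
    n_followers = out_n)
  data.table::setorder(res, trajectory)
  as_trajectory_set(res, pair_dt)
}

as_trajectory_set <- function(dt, pair_dt = NULL) {
  data.table::setattr(dt, "class",
                      c("trajectory_set", class(data.table::data.table())))
  if (!is.null(pair_dt)) data.table::setattr(dt, "pairs", pair_dt)
  dt
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d trajectories (lengths %s)\n", nrow(x),
              if (nrow(x)) paste(range(x$length), collapse = "-") else "-"))
  NextMethod()
}

#' Fill per-trajectory summary statistics
#'
#' Over each trajectory's follower set only: mean age (whole years averaged
#' as a real number) at the first code's first occurrence; per edge, the
#' mean elapsed years between consecutive first occurrences; and the number
#' of followers who died within `mortality_horizon` years of the last code's
#' first occurrence.
#'
#' @param reg a `registry` (death dates come from the patient table).
#' @param trajectories a `trajectory_set` from [build_trajectories()].
#' @param mortality_horizon years after the final diagnosis counted as
#'   trajectory-associated death (default 5).
#' @return the trajectory set with columns `mean_age_at_inception`,
#'   `edge_gap_years` (list column, one mean gap per edge) and
#'   `mortality_5y` added.
#' @export
trajectory_summary <- function(reg, trajectories, mortality_horizon = 5) {
  if (DEATH_CODE %in% unlist(trajectories$codes) &&
      !(DEATH_CODE %in% reg$events$code))
    reg <- inject_death_events(reg)
  res <- data.table::copy(trajectories)
  ages <- numeric(nrow(res)); mort <- integer(nrow(res))
  gaps <- vector("list", nrow(res))
  pat <- reg$patients
  for (i in seq_len(nrow(res))) {
    codes_i <- res$codes[[i]]
    ids <- follower_ids(reg, codes_i)
    if (!length(ids)) { ages[i] <- NA_real_; gaps[[i]] <- NA_real_; next }
    w <- follower_date_matrix(reg, codes_i)
    w <- w[patient_id %in% ids]
    d <- do.call(cbind, lapply(w[, codes_i, with = FALSE], as.numeric))
    pinfo <- merge(w[, .(patient_id)], pat, by = "patient_id", sort = FALSE)
    first_dates <- as.Date(d[, 1L], origin = "1970-01-01")
    ages[i] <- mean(age_at(first_dates, pinfo$birth_date))
    gaps[[i]] <- vapply(seq_len(length(codes_i) - 1L), function(j)
      mean(d[, j + 1L] - d[, j]) / DAYS_PER_YEAR, numeric(1))
    last_dates <- as.Date(d[, length(codes_i)], origin = "1970-01-01")
    dd <- pinfo$death_date
    mort[i] <- sum(!is.na(dd) &
                     as.numeric(dd - last_dates) <=
                       mortality_horizon * DAYS_PER_YEAR)
  }
  res[, `:=`(mean_age_at_inception = ages, edge_gap_years = gaps,
             mortality_5y = mort)]
  as_trajectory_set(res, attr(trajectories, "pairs"))
}
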