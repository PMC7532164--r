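#' @name pair-statistics
#' @title Step one: significant directional diagnosis pairs
#'
#' @description For every ordered code pair (D1, D2) the pipeline
#' (i) pre-filters by an exact binomial test of the number of D1 patients
#' who receive D2 within the pairing window against the marginal D2
#' frequency, (ii) estimates the relative risk RR = C_exposed / mean(C_i)
#' against N control samples matched on sex, age, discharge type and
#' discharge week, (iii) tests pair significance by treating each control
#' replicate as one Bernoulli comparison C_exposed vs C_i, and (iv) tests
#' directionality by an exact binomial test of D1-first vs D2-first orderings
#' among patients carrying both codes.
NULL

DAYS_PER_YEAR <- 365.25

#' Mining thresholds and matching parameters
#'
#' The two Bonferroni-corrected significance thresholds are configuration
#' defaults taken from the published analysis of the Danish registry
#' (pre-filter 1.21e-9, pair test 1.21e-8); they are not recomputed from the
#' candidate-family size.
#'
#' @param prefilter_alpha pre-filter significance level.
#' @param pair_alpha matched-comparison significance level.
#' @param direction_alpha directionality significance level.
#' @param n_controls number N of matched control replicates (the published
#'   analysis used 10,000; smaller values keep simulations cheap).
#' @param window_years pairing window in years, applied both to
#'   co-occurrence and to the directionality comparison.
#' @param min_rr minimum relative risk for a directional pair.
#' @return a `threshold_config` list.
#' @export
threshold_config <- function(prefilter_alpha = 1.21e-9,
                             pair_alpha = 1.21e-8,
                             direction_alpha = 0.05,
                             n_controls = 10000L,
                             window_years = 5,
                             min_rr = 1) {
  stopifnot(prefilter_alpha > 0, prefilter_alpha < 1,
            pair_alpha > 0, pair_alpha < 1,
            direction_alpha > 0, direction_alpha < 1,
            n_controls >= 1, window_years > 0)
  structure(list(prefilter_alpha = prefilter_alpha, pair_alpha = pair_alpha,
                 direction_alpha = direction_alpha,
                 n_controls = as.integer(n_controls),
                 window_years = window_years, min_rr = min_rr),
            class = "threshold_config")
}

#' Enumerate all ordered pairs of distinct codes
#'
#' @param codes character vector (or set) of level-3 codes.
#' @return `data.table` with columns `d1`, `d2`, all K(K-1) ordered pairs in
#'   lexicographic order.
#' @examples
#' nrow(enumerate_candidate_pairs(c("A00", "B00")))  # 2
#' @export
enumerate_candidate_pairs <- function(codes) {
  codes <- sort(unique(as.character(codes)))
  if (length(codes) < 2L)
    return(data.table::data.table(d1 = character(), d2 = character()))
  g <- data.table::CJ(d1 = codes, d2 = codes)
  g[d1 != d2][order(d1, d2)][]
}

#' Pre-filter candidate pairs by excess windowed co-occurrence
#'
#' For each ordered pair (D1, D2): among the n patients whose first D1
#' occurrence exists, counts those who receive a D2 diagnosis strictly
#' within `window_years` after it, and computes the one-sided exact binomial
#' tail P-value of that count against the null success probability given by
#' the marginal frequency of D2 in the whole patient population. A cheap,
#' conservative screen: no pair that fails the test is retained.
#'
#' @param reg a `registry` (death events already injected if death pairs are
#'   wanted).
#' @param thresholds a [threshold_config()].
#' @param keep_all if `TRUE` return all pairs with their P-values instead of
#'   only those passing `prefilter_alpha`.
#' @return `data.table` with columns `d1`, `d2`, `n_exposed`, `n_within`,
#'   `p_cooccurrence`, sorted by (`d1`, `d2`). The death code never appears
#'   as `d1`.
#' @export
prefilter_pairs <- function(reg, thresholds = threshold_config(),
                            keep_all = FALSE) {
  stopifnot(inherits(reg, "registry"))
  if (thresholds$window_years <= 0) stop("window_years must be positive")
  fo <- first_occurrences(reg)
  n_pat <- nrow(reg$patients)
  if (!nrow(fo) || n_pat == 0L)
    return(data.table::data.table(d1 = character(), d2 = character(),
                                  n_exposed = integer(), n_within = integer(),
                                  p_cooccurrence = numeric()))
  wdays <- thresholds$window_years * DAYS_PER_YEAR
  counts <- fo[, .(n_code = .N), by = code]
  ## anchor = first occurrence of d1; a patient counts for (d1, d2) when any
  ## d2 event falls strictly within the window after that anchor
  co <- merge(fo, reg$events[, .(patient_id, code, date)],
              by = "patient_id", allow.cartesian = TRUE,
              suffixes = c("", ".y"))
  co <- co[code != code.y]
  dt_days <- as.numeric(co$date - co$first_date)
  co <- co[dt_days > 0 & dt_days <= wdays]
  within <- unique(co[, .(patient_id, d1 = code, d2 = code.y)])[
    , .(n_within = .N), by = .(d1, d2)]
  pairs <- data.table::CJ(d1 = counts$code, d2 = counts$code)[d1 != d2]
  pairs <- merge(pairs, counts[, .(d1 = code, n_exposed = n_code)], by = "d1")
  pairs <- merge(pairs, counts[, .(d2 = code, n_code)], by = "d2")
  pairs <- merge(pairs, within, by = c("d1", "d2"), all.x = TRUE)
  pairs[is.na(n_within), n_within := 0L]
  pairs[, p0 := n_code / n_pat]
  pairs[, p_cooccurrence := stats::pbinom(n_within - 1L, n_exposed, p0,
                                          lower.tail = FALSE)]
  pairs[n_within == 0L, p_cooccurrence := 1]
  pairs <- pairs[d1 != DEATH_CODE]
  pairs[, `:=`(n_code = NULL, p0 = NULL)]
  data.table::setorder(pairs, d1, d2)
  if (!keep_all) pairs <- pairs[p_cooccurrence < thresholds$prefilter_alpha]
  pairs[]
}

## ---------------------------------------------------------------------
## matched-control machinery

## per-event matching covariates for anchor events / candidate pool
event_match_keys <- function(events, patients) {
  m <- merge(events, patients[, .(patient_id, sex, birth_date)],
             by = "patient_id")
  m[, age := age_at(date, birth_date)]
  m[, quarter := pmin((week - 1L) %/% 13L, 3L)]
  m[, birth_date := NULL]
  m
}

#' Draw matched control counts for one diagnosis pair
#'
#' Each exposed patient (anchored at their first `d1` event) is matched to
#' control individuals drawn uniformly from non-exposed patients having at
#' least one event with the same matching key (sex, whole-year age at the
#' event, discharge type, ISO week). When the full key has an empty pool the
#' week is relaxed to the calendar quarter, then dropped, then discharge
#' type and age are dropped in turn; the last resort is any non-exposed
#' patient event. Every relaxation is counted in the returned `tiers`
#' vector. For replicate i in 1..N, `C_i` is the number of sampled controls
#' who receive a `d2` diagnosis within `window_years` of their matched
#' event date; `c_exposed` is the same count over the exposed patients
#' themselves.
#'
#' @param reg a `registry`.
#' @param d1,d2 codes.
#' @param n_controls number of control replicates N.
#' @param window_years pairing window (years).
#' @param seed integer seed; identical seeds give identical counts.
#' @return list with `c_exposed`, `control_counts` (length N), `n_exposed`,
#'   and `tiers` (how many exposed anchors matched at each relaxation level).
#' @export
sample_matched_controls <- function(reg, d1, d2, n_controls = 100L,
                                    window_years = 5, seed = 1L) {
  stopifnot(inherits(reg, "registry"), n_controls >= 1)
  set.seed(seed)
  wdays <- window_years * DAYS_PER_YEAR
  ev <- reg$events
  if (!any(ev$code == d1))
    stop("no patient carries code ", d1, call. = FALSE)
  exposed_first <- ev[code == d1, .(anchor_date = min(date)), by = patient_id]
  ## the anchor event row (earliest d1 event; deterministic tie-break)
  anchors <- ev[code == d1][exposed_first, on = .(patient_id, date = anchor_date),
                            mult = "first"]
  anchors <- event_match_keys(anchors, reg$patients)
  ## any d2 event strictly within the window after an anchor date
  d2_ev <- ev[code == d2, .(patient_id, d2_date = date)]
  any_d2_within <- function(dt) {
    if (!nrow(dt)) return(logical(0))
    dt <- data.table::copy(dt)[, row_id := .I]
    hits <- merge(dt[, .(row_id, patient_id, date)], d2_ev,
                  by = "patient_id", allow.cartesian = TRUE)
    g <- as.numeric(hits$d2_date - hits$date)
    hit_rows <- unique(hits$row_id[g > 0 & g <= wdays])
    seq_len(nrow(dt)) %in% hit_rows
  }
  c_exposed <- sum(any_d2_within(anchors))
  ## candidate pool: events of non-exposed patients
  pool <- ev[!patient_id %in% exposed_first$patient_id & code != DEATH_CODE]
  tiers <- c(week = 0L, quarter = 0L, no_week = 0L, sex_dtype = 0L,
             any = 0L, unmatched = 0L)
  if (!nrow(pool)) {
    tiers["unmatched"] <- nrow(anchors)
    return(list(c_exposed = c_exposed,
                control_counts = rep(0L, n_controls),
                n_exposed = nrow(anchors), tiers = tiers))
  }
  pool <- event_match_keys(pool, reg$patients)
  pool[, has_d2 := any_d2_within(pool)]
  ## success fraction of each pool cell at every relaxation tier
  tier_defs <- list(
    week = c("sex", "age", "discharge_type", "week"),
    quarter = c("sex", "age", "discharge_type", "quarter"),
    no_week = c("sex", "age", "discharge_type"),
    sex_dtype = c("sex", "discharge_type"))
  q <- rep(NA_real_, nrow(anchors))
  level <- rep(NA_character_, nrow(anchors))
  for (tn in names(tier_defs)) {
    need <- which(is.na(q))
    if (!length(need)) break
    cols <- tier_defs[[tn]]
    cell <- pool[, .(pool_q = mean(has_d2)), by = cols]
    hit <- merge(anchors[need, ..cols][, key_ := .I], cell,
                 by = cols, all.x = TRUE, sort = FALSE)
    data.table::setorder(hit, key_)
    q[need] <- hit$pool_q
    level[need[!is.na(hit$pool_q)]] <- tn
  }
  still <- which(is.na(q))
  if (length(still)) {
    q[still] <- mean(pool$has_d2)
    level[still] <- "any"
  }
  tiers[names(tiers)] <- 0L
  tl <- table(level)
  tiers[names(tl)] <- as.integer(tl)
  ## C_i = sum over exposed anchors of Bernoulli(q_j); drawing a uniform
  ## pool member and testing its d2 indicator is exactly Bernoulli(q_j),
  ## so counts are sampled groupwise as binomials
  qt <- table(q)
  qs <- as.numeric(names(qt))
  control_counts <- rep(0L, n_controls)
  for (g in seq_along(qs))
    control_counts <- control_counts +
      stats::rbinom(n_controls, size = as.integer(qt[g]), prob = qs[g])
  list(c_exposed = c_exposed, control_counts = control_counts,
       n_exposed = nrow(anchors), tiers = tiers)
}

#' Matched-control relative risk
#'
#' RR = C_exposed / mean(C_1..C_N). A positive count over an all-zero
#' control ensemble returns `Inf` (ranked above any finite RR); both zero is
#' an error — such a pair should never have survived the pre-filter.
#'
#' @param c_exposed count of exposed patients receiving D2 in the window.
#' @param control_counts integer vector of control replicate counts.
#' @return the relative risk.
#' @examples
#' relative_risk(10, c(5, 5, 5, 5))  # 2
#' @export
relative_risk <- function(c_exposed, control_counts) {
  if (!length(control_counts)) stop("control_counts is empty", call. = FALSE)
  m <- mean(control_counts)
  if (m == 0) {
    if (c_exposed == 0)
      stop("relative risk undefined: exposed and control counts all zero",
           call. = FALSE)
    return(Inf)
  }
  c_exposed / m
}

#' Exact binomial pair significance against matched controls
#'
#' Each control replicate is one Bernoulli comparison: a success when
#' `c_exposed > C_i`, a half-success on a tie. Returns the one-sided exact
#' binomial tail probability of at least the attained number of successes in
#' N trials at success probability 1/2 (excess risk alternative).
#'
#' @inheritParams relative_risk
#' @return a P-value in (0, 1].
#' @export
pair_significance <- function(c_exposed, control_counts) {
  n <- length(control_counts)
  stopifnot(n >= 1)
  s <- sum(c_exposed > control_counts) + 0.5 * sum(c_exposed == control_counts)
  k_min <- as.integer(ceiling(s - 1e-9))
  stats::pbinom(k_min - 1L, n, 0.5, lower.tail = FALSE)
}

## low-tail analogue, used for the downloadable RR < 1 pairs
pair_significance_deficit <- function(c_exposed, control_counts) {
  n <- length(control_counts)
  s <- sum(c_exposed > control_counts) + 0.5 * sum(c_exposed == control_counts)
  stats::pbinom(as.integer(floor(s + 1e-9)), n, 0.5, lower.tail = TRUE)
}

#' Directionality test for an ordered pair
#'
#' Among patients whose first occurrences of both codes exist and lie within
#' `window_years` of each other, counts how often `d1` came strictly first
#' versus `d2`; same-day first occurrences carry no direction and are
#' excluded. Returns the one-sided exact binomial P-value of the D1-first
#' count out of the usable total at probability 1/2.
#'
#' @param reg a `registry`.
#' @param d1,d2 codes.
#' @param window_years maximum separation of the two first occurrences.
#' @return list with `n_d1_first`, `n_d2_first` and `p_direction` (`NA` when
#'   no patient is usable).
#' @export
directionality_test <- function(reg, d1, d2, window_years = 5) {
  stopifnot(inherits(reg, "registry"))
  fo <- first_occurrences(reg)
  a <- fo[code == d1]; bb <- fo[code == d2]
  m <- merge(a[, .(patient_id, t1 = first_date)],
             bb[, .(patient_id, t2 = first_date)], by = "patient_id")
  gap <- as.numeric(m$t2 - m$t1)
  usable <- abs(gap) <= window_years * DAYS_PER_YEAR & gap != 0
  n1 <- sum(usable & gap > 0)
  n2 <- sum(usable & gap < 0)
  p <- if (n1 + n2 == 0) NA_real_
       else stats::pbinom(n1 - 1L, n1 + n2, 0.5, lower.tail = FALSE)
  list(n_d1_first = n1, n_d2_first = n2, p_direction = p)
}

#' Mine statistically significant directional diagnosis pairs
#'
#' Runs the full first step: optional sex restriction, chapter filtering,
#' death-code injection, co-occurrence pre-filter, matched-control relative
#' risk, exact binomial pair significance and the directionality test. A
#' pair (D1, D2) is directional when it passes the pre-filter, its matched
#' pair test is below `pair_alpha`, RR exceeds `min_rr` and D1-before-D2
#' dominates at `direction_alpha`. Pairs whose matched comparison is
#' significantly *below* the controls (RR < 1) are returned separately.
#'
#' @param reg a `registry`.
#' @param thresholds a [threshold_config()].
#' @param sex_filter "all", "male" or "female": restrict the population
#'   before mining (sex-specific trajectories).
#' @param seed integer seed driving the matched sampling.
#' @param excluded_chapters chapters dropped before mining.
#' @param inject_deaths add `Y99` death events so D1 -> death pairs are
#'   minable (default `TRUE`).
#' @return an object of class `directional_pairs`: list with
#'   * `pairs` — `data.table` of directional pairs (columns `d1`, `d2`,
#'     `n_exposed`, `c_exposed`, `mean_control_count`, `rr`,
#'     `p_cooccurrence`, `n_d1_first`, `n_d2_first`, `p_direction`,
#'     `p_pair`),
#'   * `rr_below_1` — significant pairs with RR < 1 (deficit tail),
#'   * `stage_counts` — candidates, prefiltered, significant, directional,
#'   * `thresholds`, `sex_filter`, `seed`.
#' @export
mine_directional_pairs <- function(reg, thresholds = threshold_config(),
                                   sex_filter = c("all", "male", "female"),
                                   seed = 1L,
                                   excluded_chapters = DEFAULT_EXCLUDED_CHAPTERS,
                                   inject_deaths = TRUE) {
  sex_filter <- match.arg(sex_filter)
  stopifnot(inherits(reg, "registry"), inherits(thresholds, "threshold_config"))
  if (sex_filter != "all") {
    keep <- reg$patients[sex == sex_filter, patient_id]
    reg <- new_registry(reg$patients[patient_id %in% keep],
                        reg$events[patient_id %in% keep],
                        window = reg$window, validate = FALSE)
  }
  reg <- new_registry(reg$patients,
                      filter_chapters(reg$events, excluded_chapters),
                      window = reg$window, validate = FALSE)
  if (inject_deaths) reg <- inject_death_events(reg, thresholds$window_years)
  codes <- setdiff(unique(reg$events$code), DEATH_CODE)
  n_candidates <- length(codes) * max(length(codes) - 1L, 0L) +
    if (DEATH_CODE %in% reg$events$code) length(codes) else 0L
  pre <- prefilter_pairs(reg, thresholds)
  empty_cols <- function() data.table::data.table(
    d1 = character(), d2 = character(), n_exposed = integer(),
    c_exposed = integer(), mean_control_count = numeric(), rr = numeric(),
    p_cooccurrence = numeric(), n_d1_first = integer(),
    n_d2_first = integer(), p_direction = numeric(), p_pair = numeric())
  rows <- list(); low_rows <- list()
  n_signif <- 0L
  if (nrow(pre)) {
    set.seed(seed)
    pair_seeds <- sample.int(.Machine$integer.max - 1L, nrow(pre))
    for (i in seq_len(nrow(pre))) {
      mc <- sample_matched_controls(reg, pre$d1[i], pre$d2[i],
                                    n_controls = thresholds$n_controls,
                                    window_years = thresholds$window_years,
                                    seed = pair_seeds[i])
      if (mc$c_exposed == 0 && mean(mc$control_counts) == 0) next
      rr <- relative_risk(mc$c_exposed, mc$control_counts)
      p_pair <- pair_significance(mc$c_exposed, mc$control_counts)
      p_low <- pair_significance_deficit(mc$c_exposed, mc$control_counts)
      row <- data.table::data.table(
        d1 = pre$d1[i], d2 = pre$d2[i], n_exposed = mc$n_exposed,
        c_exposed = mc$c_exposed,
        mean_control_count = mean(mc$control_counts), rr = rr,
        p_cooccurrence = pre$p_cooccurrence[i],
        n_d1_first = NA_integer_, n_d2_first = NA_integer_,
        p_direction = NA_real_, p_pair = p_pair)
      if (p_pair < thresholds$pair_alpha) {
        n_signif <- n_signif + 1L
        dir <- directionality_test(reg, pre$d1[i], pre$d2[i],
                                   thresholds$window_years)
        row[, `:=`(n_d1_first = dir$n_d1_first, n_d2_first = dir$n_d2_first,
                   p_direction = dir$p_direction)]
        if (!is.na(dir$p_direction) &&
            dir$p_direction < thresholds$direction_alpha &&
            rr > thresholds$min_rr)
          rows[[length(rows) + 1L]] <- row
      }
      if (p_low < thresholds$pair_alpha && rr < 1)
        low_rows[[length(low_rows) + 1L]] <- row
    }
  }
  pairs <- if (length(rows)) data.table::rbindlist(rows) else empty_cols()
  low <- if (length(low_rows)) data.table::rbindlist(low_rows) else empty_cols()
  data.table::setorder(pairs, d1, d2)
  structure(list(
    pairs = pairs, rr_below_1 = low,
    stage_counts = c(candidates = n_candidates, prefiltered = nrow(pre),
                     significant = n_signif, directional = nrow(pairs)),
    thresholds = thresholds, sex_filter = sex_filter, seed = seed),
    class = "directional_pairs")
}

#' @export
print.directional_pairs <- function(x, ...) {
  sc <- x$stage_counts
  cat(sprintf(paste0("<directional_pairs> %d directional pair(s) ",
                     "(candidates %d -> prefiltered %d -> significant %d ",
                     "-> directional %d; sex=%s)\n"),
              nrow(x$pairs), sc[["candidates"]], sc[["prefiltered"]],
              sc[["significant"]], sc[["directional"]], x$sex_filter))
  if (nrow(x$pairs)) print(x$pairs)
  invisible(x)
}
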