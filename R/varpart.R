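#' Seasonal site means of daily fluxes
#'
#' Averages daily values per site and year over a season, keeping a
#' site-year only when at least 80% of the season's days carry a value, then
#' averages the qualifying years per site. The yearly timescale applies the
#' same coverage rule over the 365-day year; monthly seasons over the days
#' of that calendar month (Feb 29 is dropped throughout).
#'
#' @param daily wide daily table (from [derive_radiation()] /
#'   [normalize_fluxes()]).
#' @param season `"JJA"`, `"Y"`, or a calendar month number 1-12.
#' @param responses response columns to average.
#' @param min_coverage minimum fraction of season days with values.
#' @param year_range optional inclusive `c(min, max)` year filter.
#' @return Long tibble: `site_id`, `response`, `value`, `n_years`,
#'   `mean_coverage`.
#' @export
seasonal_site_means <- function(daily, season = "JJA",
                                responses = intersect(RESPONSE_NAMES,
                                                      names(daily)),
                                min_coverage = 0.8, year_range = NULL) {
  d <- daily |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y")),
                  doy = doy_noleap(.data$date),
                  month = as.integer(format(.data$date, "%m"))) |>
    dplyr::filter(!is.na(.data$doy))
  if (!is.null(year_range)) {
    d <- dplyr::filter(d, .data$year >= year_range[1],
                       .data$year <= year_range[2])
  }
  if (identical(season, "JJA")) {
    d <- dplyr::filter(d, .data$doy %in% JJA_DOYS)
    season_len <- length(JJA_DOYS)
  } else if (identical(season, "Y")) {
    season_len <- 365
  } else if (is.numeric(season) && season %in% 1:12) {
    d <- dplyr::filter(d, .data$month == season)
    season_len <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[season]
  } else {
    stop("unknown season label: ", season,
         "; use \"JJA\", \"Y\" or a month number 1-12", call. = FALSE)
  }
  purrr::map_dfr(responses, function(resp) {
    d |>
      dplyr::group_by(.data$site_id, .data$year) |>
      dplyr::summarise(n_days = sum(!is.na(.data[[resp]])),
                       value = mean(.data[[resp]], na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(coverage = .data$n_days / season_len) |>
      dplyr::filter(.data$coverage >= min_coverage) |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(response = resp, value = mean(.data$value),
                       n_years = dplyr::n(),
                       mean_coverage = mean(.data$coverage),
                       .groups = "drop")
  })
}

#' @rdname seasonal_site_means
#' @param site_means long output of [seasonal_site_means()].
#' @return `seasonal_site_means_wide()`: `site_id` plus one column per
#'   response.
#' @export
seasonal_site_means_wide <- function(site_means) {
  tidyr::pivot_wider(site_means[, c("site_id", "response", "value")],
                     names_from = "response", values_from = "value")
}

# R-squared of an OLS fit with intercept; NULL if the design is aliased
ols_r2 <- function(data, response, predictors) {
  X <- model.matrix(stats::reformulate(predictors), data = data)
  fit <- lm.fit(X, data[[response]])
  if (any(is.na(fit$coefficients))) return(NULL)
  y <- data[[response]]
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Variance partition of one predictor pair
#'
#' For an ordinary least-squares model of a response on two predictors,
#' quantifies each predictor's explained variance (% of total) when fitted
#' first (`100 * R2(A)`), when fitted last
#' (`100 * [R2(A,B) - R2(B)]`), and averaged over the two orderings. With
#' exactly two predictors this ordering average is the LMG/dominance
#' decomposition. Categorical predictors enter as full dummy blocks, so
#' their share is the block's joint contribution. Negative last-shares
#' (possible under suppression) are retained in `last` and `average_raw`
#' and floored at zero in `average`.
#'
#' @param data data frame holding the columns; incomplete rows are dropped.
#' @param response response column name.
#' @param driver_a,driver_b predictor column names.
#' @param min_extra_obs required observations beyond the number of fitted
#'   coefficients.
#' @return Two-row tibble (one per driver): `first`, `last`, `average_raw`,
#'   `average`, `r2_pair` (all in % of variance), `n_sites`; or `NULL` with
#'   a warning when the design is aliased or too small.
#' @export
partition_pair <- function(data, response, driver_a, driver_b,
                           min_extra_obs = 3) {
  cols <- c(response, driver_a, driver_b)
  d <- data[complete.cases(data[, cols]), cols]
  d <- droplevels(d)
  p <- ncol(model.matrix(stats::reformulate(c(driver_a, driver_b)), data = d))
  if (nrow(d) < p + min_extra_obs) {
    warning("pair (", driver_a, ", ", driver_b, ") for ", response,
            " skipped: ", nrow(d), " observations for ", p, " coefficients")
    return(NULL)
  }
  r2_a <- ols_r2(d, response, driver_a)
  r2_b <- ols_r2(d, response, driver_b)
  r2_ab <- ols_r2(d, response, c(driver_a, driver_b))
  if (is.null(r2_a) || is.null(r2_b) || is.null(r2_ab)) {
    warning("pair (", driver_a, ", ", driver_b, ") for ", response,
            " skipped: aliased design")
    return(NULL)
  }
  mk <- function(driver, own, other) {
    first <- 100 * own
    last <- 100 * (r2_ab - other)
    tibble::tibble(driver = driver, first = first, last = last,
                   average_raw = (first + last) / 2,
                   average = (first + pmax(last, 0)) / 2,
                   r2_pair = 100 * r2_ab, n_sites = nrow(d))
  }
  dplyr::bind_rows(mk(driver_a, r2_a, r2_b), mk(driver_b, r2_b, r2_a))
}

#' All-pairs variance partitioning over the SEB-driver set
#'
#' Fits every 2-predictor OLS model over the driver set for each response
#' (105 unordered pairs for 15 drivers; each pair evaluated in both
#' predictor orders) and summarizes, per driver and response, the mean,
#' minimum and maximum of the ordering-averaged explained variance across
#' the driver's pairs. Sites with a missing driver are dropped listwise per
#' pair, not globally.
#'
#' @param data frame with `site_id`, driver columns and response columns
#'   (e.g. [seasonal_site_means_wide()] joined to [build_driver_table()]).
#' @param drivers driver column names (default the canonical 15).
#' @param responses response column names present in `data`.
#' @param site_years optional named vector (by `site_id`) of site-year
#'   counts used for the `mean_site_years` bookkeeping.
#' @return Tibble: `response`, `driver`, `mean_explained`, `min_explained`,
#'   `max_explained`, `n_models`, `mean_sites`, `mean_site_years`.
#'   Attribute `"counts"` holds per-response pair/model counts; attributes
#'   `"n_pairs_unique"` and `"n_model_evaluations"` the totals.
#' @export
run_all_pairs <- function(data, drivers = DRIVER_NAMES,
                          responses = intersect(RESPONSE_NAMES, names(data)),
                          site_years = NULL) {
  missing_drv <- setdiff(drivers, names(data))
  if (length(missing_drv) > 0) {
    stop("missing driver column(s): ", paste(missing_drv, collapse = ", "),
         call. = FALSE)
  }
  missing_resp <- setdiff(responses, names(data))
  if (length(missing_resp) > 0) {
    stop("missing response column(s): ", paste(missing_resp, collapse = ", "),
         call. = FALSE)
  }
  pairs <- utils::combn(drivers, 2, simplify = FALSE)
  per_resp <- purrr::map(responses, function(resp) {
    shares <- purrr::map_dfr(pairs, function(pr) {
      out <- partition_pair(data, resp, pr[1], pr[2])
      if (is.null(out)) return(NULL)
      out$pair_id <- paste(pr, collapse = "|")
      if (!is.null(site_years)) {
        used <- data$site_id[complete.cases(data[, c(resp, pr)])]
        out$site_years <- sum(site_years[used], na.rm = TRUE)
      } else {
        out$site_years <- NA_real_
      }
      out
    })
    n_pairs_fitted <- length(unique(shares$pair_id))
    summary <- shares |>
      dplyr::group_by(.data$driver) |>
      dplyr::summarise(
        response = resp,
        mean_explained = mean(.data$average),
        min_explained = min(.data$average),
        max_explained = max(.data$average),
        n_models = 2L * dplyr::n(),
        mean_sites = mean(.data$n_sites),
        mean_site_years = mean(.data$site_years),
        .groups = "drop"
      )
    list(summary = summary,
         counts = tibble::tibble(response = resp,
                                 n_pairs = n_pairs_fitted,
                                 n_models = 2L * n_pairs_fitted))
  })
  res <- dplyr::bind_rows(purrr::map(per_resp, "summary")) |>
    dplyr::select("response", "driver", dplyr::everything())
  counts <- dplyr::bind_rows(purrr::map(per_resp, "counts"))
  attr(res, "counts") <- counts
  attr(res, "n_pairs_unique") <- length(pairs)
  attr(res, "n_model_evaluations") <- sum(counts$n_models)
  res
}

#' Rank drivers by mean explained variance for one response
#'
#' @param varpart result of [run_all_pairs()].
#' @param response response name.
#' @return The rows for `response`, sorted by decreasing `mean_explained`.
#' @export
rank_drivers <- function(varpart, response) {
  varpart |>
    dplyr::filter(.data$response == .env$response) |>
    dplyr::arrange(dplyr::desc(.data$mean_explained))
}
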