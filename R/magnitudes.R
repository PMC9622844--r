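#' Per-vegetation-type flux magnitudes from a linear mixed model
#'
#' Models site-level seasonal flux means as a function of vegetation type
#' (fixed effect) with the data-distribution network as a random intercept,
#' fitted by REML. Per-type estimated marginal means with 95% confidence
#' intervals come from the fitted model; the omnibus vegetation-type effect
#' is a type-III F-test with Satterthwaite denominator degrees of freedom.
#' When fewer than two networks are present the random effect is dropped
#' and the model degenerates to a one-way fixed-effects ANOVA on site
#' means, whose per-type estimates equal ordinary means of site means. The
#' omnibus effect is flagged as not shown when three or more of the seven
#' canonical vegetation classes are absent.
#'
#' @param site_means one row per site with the response in `value` (e.g.
#'   one response of [seasonal_site_means()]).
#' @param metadata site table with `site_id`, `vegetation_type`, `network`.
#' @param df_method denominator-df method passed to the mixed-model ANOVA
#'   (`"Satterthwaite"` or `"Kenward-Roger"`); the df approximation is
#'   software-specific, so it is kept configurable.
#' @return A `magnitude_fit` list: `estimates` (tibble of per-type `mean`,
#'   `ci95_halfwidth`, `df`), `effect` (one-row tibble `F`, `df_num`,
#'   `df_den`, `p_value`, `effect_shown`), `model`, and `engine`
#'   (`"lmer"` or `"lm"`).
#' @export
fit_magnitude_model <- function(site_means, metadata,
                                df_method = "Satterthwaite") {
  d <- site_means |>
    dplyr::inner_join(metadata[, c("site_id", "vegetation_type", "network")],
                      by = "site_id") |>
    dplyr::filter(!is.na(.data$value))
  d$vegetation_type <- factor(d$vegetation_type)
  if (nlevels(d$vegetation_type) < 2) {
    stop("need at least two vegetation types with data", call. = FALSE)
  }
  absent <- setdiff(VEGETATION_TYPES, levels(d$vegetation_type))

  if (length(unique(d$network)) < 2) {
    model <- lm(value ~ vegetation_type, data = d)
    engine <- "lm"
    aov_tab <- anova(model)
    eff <- tibble::tibble(F = aov_tab$`F value`[1],
                          df_num = aov_tab$Df[1], df_den = aov_tab$Df[2],
                          p_value = aov_tab$`Pr(>F)`[1])
  } else {
    model <- lmerTest::lmer(value ~ vegetation_type + (1 | network), data = d)
    engine <- "lmer"
    aov_tab <- stats::anova(model, type = 3, ddf = df_method)
    eff <- tibble::tibble(F = aov_tab$`F value`[1],
                          df_num = aov_tab$NumDF[1], df_den = aov_tab$DenDF[1],
                          p_value = aov_tab$`Pr(>F)`[1])
  }
  eff$effect_shown <- length(absent) < 3
  emm <- emmeans::emmeans(model, "vegetation_type")
  es <- as.data.frame(emm)
  estimates <- tibble::tibble(
    vegetation_type = as.character(es$vegetation_type),
    mean = es$emmean,
    se = es$SE,
    df = es$df,
    ci95_halfwidth = es$upper.CL - es$emmean,
    n_sites = as.integer(table(d$vegetation_type)[es$vegetation_type])
  )
  structure(list(estimates = estimates, effect = eff, model = model,
                 emmeans = emm, engine = engine, absent_types = absent),
            class = "magnitude_fit")
}

#' Bonferroni-adjusted pairwise vegetation-type contrasts
#'
#' All pairwise differences of the per-type estimated marginal means, with
#' p-values multiplied by the number of comparisons (capped at 1).
#'
#' @param fit a [fit_magnitude_model()] result.
#' @return Tibble: `contrast`, `difference`, `se`, `df`, `p_adjusted`.
#' @export
pairwise_posthoc <- function(fit) {
  ct <- as.data.frame(emmeans::contrast(fit$emmeans, method = "pairwise",
                                        adjust = "bonferroni"))
  tibble::tibble(contrast = as.character(ct$contrast),
                 difference = ct$estimate, se = ct$SE, df = ct$df,
                 p_adjusted = ct$p.value)
}

#' Bowen ratio
#'
#' Ratio of sensible to latent heat flux, H / LE. Energy partitioning is
#' sensible-heat-dominated when the ratio exceeds 1. When LE is zero the
#' numeric ratio is undefined (`NA`); [format_bowen()] renders such cases,
#' and negative ratios, as `"<0"` in the conventional display style.
#'
#' @param H_mean,LE_mean mean sensible and latent heat flux (W m-2).
#' @return The ratio (vectorized); `NA` where `LE_mean == 0`.
#' @export
#' @examples
#' round(bowen_ratio(39, 24), 1) # 1.6
#' round(bowen_ratio(26, 47), 1) # 0.6
bowen_ratio <- function(H_mean, LE_mean) {
  ifelse(LE_mean == 0, NA_real_, H_mean / LE_mean)
}

#' @rdname bowen_ratio
#' @param digits display rounding.
#' @return `format_bowen()`: character; `"<0"` for negative or undefined
#'   (H < 0 with LE = 0) partitionings.
#' @export
format_bowen <- function(H_mean, LE_mean, digits = 1) {
  ratio <- bowen_ratio(H_mean, LE_mean)
  dplyr::case_when(
    is.na(ratio) & H_mean < 0 ~ "<0",
    is.na(ratio) ~ "undefined",
    ratio < 0 ~ "<0",
    TRUE ~ formatC(round(ratio, digits), format = "f", digits = digits)
  )
}

#' Magnitude table across fluxes
#'
#' Runs [fit_magnitude_model()] for every requested response of a seasonal
#' site-mean table and stacks per-type estimates and omnibus tests into the
#' layout of a per-season magnitude table.
#'
#' @param site_means long output of [seasonal_site_means()].
#' @param metadata site table.
#' @param responses responses to fit (default: all present).
#' @param season label recorded in the output.
#' @return List with `estimates` and `effects` tibbles.
#' @export
magnitude_table <- function(site_means, metadata,
                            responses = unique(site_means$response),
                            season = "JJA") {
  fits <- purrr::map(responses, function(resp) {
    sm <- dplyr::filter(site_means, .data$response == resp)
    if (nrow(sm) < 3 || length(unique(
      metadata$vegetation_type[match(sm$site_id, metadata$site_id)])) < 2) {
      return(NULL)
    }
    fit <- fit_magnitude_model(sm, metadata)
    list(est = dplyr::mutate(fit$estimates, flux = resp, season = season,
                             .before = 1),
         eff = dplyr::mutate(fit$effect, flux = resp, season = season,
                             .before = 1))
  })
  fits <- purrr::compact(fits)
  list(estimates = dplyr::bind_rows(purrr::map(fits, "est")),
       effects = dplyr::bind_rows(purrr::map(fits, "eff")))
}
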