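# End-to-end analysis chain: bioclimatic indices -> vintage PCA -> score
# trends -> partial correlations with year as control -> Kruskal-Wallis
# by vintage rating -> tercile composites (station variables, regional
# LAI, teleconnection indices) -> seasonal SST correlation map.

#' Pipeline configuration
#'
#' Consolidates the window definitions, thresholds and resampling
#' parameters of the full analysis: growing season April-October,
#' heliothermal window April-September, cool-night month September,
#' dryness-index window April-September, SST window previous
#' December-May; hot/frost/wet-day thresholds 30 degC / 0 degC / 1 mm;
#' vineyard-fraction threshold 0.75; 10,000 bootstrap samples with
#' 5th/95th percentile envelopes; alpha 0.05.
#'
#' @param latitude Station latitude, degrees north.
#' @param n_boot,percentiles Bootstrap envelope parameters.
#' @param alpha Significance level for correlations and tests.
#' @param vineyard_threshold Minimum vineyard fraction for LAI pixels.
#' @param n_components PCA components to retain.
#' @param seed Master seed; every stochastic stage derives its stream
#'   from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(latitude = 42.45, n_boot = 10000L,
                            percentiles = c(5, 95), alpha = 0.05,
                            vineyard_threshold = 0.75,
                            n_components = 3L, seed = 1L) {
  stopifnot(is.finite(latitude), n_boot >= 100, alpha > 0, alpha < 1)
  structure(list(latitude = latitude, n_boot = as.integer(n_boot),
                 percentiles = percentiles, alpha = alpha,
                 vineyard_threshold = vineyard_threshold,
                 n_components = as.integer(n_components),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# monthly long series of one station variable from the monthly aggregate
.monthly_series <- function(monthly, col) {
  data.frame(year = monthly$year, month = monthly$month,
             value = monthly[[col]])
}

#' Run the full climate-wine analysis chain
#'
#' With `inputs = NULL` the bundled generators produce all inputs from
#' the master seed (daily weather, vintage table, LAI grid with
#' vineyard fractions, teleconnection indices with a May-EA coupling to
#' May TX, drought-index proxy, and an SST field driven by the leading
#' vintage component). Alternatively `inputs` supplies real data as a
#' list with elements `weather`, `vintage`, `spei` (optional), `lai`
#' (optional, with a `fractions` attribute or element), `teleconnections`
#' (optional), `sst` (optional).
#'
#' Stages: annual bioclimatic table; PCA of the vintage table; trend
#' report per component; partial correlations (year as control) between
#' each component and every bioclimatic index; Kruskal-Wallis (plus
#' pairwise follow-up) of component scores across vintage-rating
#' categories; tercile composites with bootstrap envelopes for the
#' monthly station variables, the regional LAI series and the
#' teleconnection indices, against the extreme years of PC1; and the
#' correlation map between detrended PC1 and the previous-December-to-May
#' SST field. Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param inputs Optional list of real inputs (see Details).
#' @param out_dir Optional directory; when given, every result table is
#'   written as CSV together with a JSON manifest (config, seed,
#'   package version).
#' @return A list bundle with elements `bioclim`, `pca`, `trends`,
#'   `partial_correlations`, `kruskal_wallis`, `composites` (per station
#'   variable), `lai` (regional series + composite), `teleconnections`
#'   (composite per index), `sst_map`, and `manifest`.
#' @export
run_report <- function(config = pipeline_config(), inputs = NULL,
                       out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  synthetic <- is.null(inputs)
  weather <- stage("weather", {
    if (synthetic) generate_daily_weather(weather_gen_config(), seed = seed)
    else inputs$weather
  })
  monthly <- aggregate_monthly(weather)

  bioclim <- stage("bioclim", {
    spei <- if (synthetic) generate_spei_proxy(weather, config$latitude)
            else inputs$spei
    bioclim_table(weather, latitude = config$latitude, spei = spei)
  })

  vintage <- stage("vintage", {
    if (synthetic) generate_wine_table(weather, vintage_response_config(),
                                       seed = seed + 1L)
    else inputs$vintage
  })

  pca <- stage("pca", run_pca(vintage, n_components = config$n_components))
  trends <- stage("trends", lapply(seq_len(config$n_components),
                                   function(k) score_trend_report(pca, k)))
  names(trends) <- paste0("PC", seq_len(config$n_components))

  pcor <- stage("partial_correlations", {
    idx_cols <- setdiff(names(bioclim), "year")
    rows <- list()
    for (k in seq_len(config$n_components)) {
      sc <- pca$scores[[paste0("PC", k)]]
      yrs <- pca$scores$year
      for (v in idx_cols) {
        b <- bioclim[[v]][match(yrs, bioclim$year)]
        ok <- is.finite(b) & is.finite(sc)
        if (sum(ok) < 4) next
        pc <- partial_correlation(sc[ok], b[ok], control = yrs[ok])
        rows[[length(rows) + 1L]] <- data.frame(
          component = paste0("PC", k), index = v,
          r_partial = pc$r_partial, p_value = pc$p_value, n = pc$n)
      }
    }
    out <- do.call(rbind, rows)
    out$p_holm <- stats::ave(out$p_value, out$component,
                             FUN = function(p) stats::p.adjust(p, "holm"))
    out
  })

  kw <- stage("kruskal_wallis", {
    lapply(seq_len(config$n_components), function(k) {
      sc <- pca$scores[[paste0("PC", k)]]
      rating <- vintage$rating[match(pca$scores$year, vintage$year)]
      groups <- split(sc, droplevels(rating))
      if (length(groups) < 2L) return(NULL)
      res <- kruskal_wallis(groups)
      res$pairwise <- if (length(groups) >= 2L)
        conover_iman(groups, alpha = config$alpha) else NULL
      res
    })
  })
  names(kw) <- paste0("PC", seq_len(config$n_components))

  pc1 <- data.frame(year = pca$scores$year, value = pca$scores$PC1)
  station_vars <- c(tx = "tx", tn = "tn", pp_total = "pp_total",
                    wet_days = "wet_days", ss = "ss", hr = "hr")
  composites <- stage("composites", {
    lapply(station_vars, function(v)
      composite_report(.monthly_series(monthly, v), pc1,
                       n_boot = config$n_boot,
                       percentiles = config$percentiles,
                       seed = seed + 2L))
  })

  lai <- stage("lai", {
    grid <- if (synthetic) generate_lai_grid(lai_gen_config(), weather,
                                             seed = seed + 3L)
            else inputs$lai
    if (is.null(grid)) NULL else {
      fr <- attr(grid, "fractions") %||% inputs$fractions
      mask <- select_vineyard_pixels(fr, config$vineyard_threshold)
      reg <- regional_lai_series(grid, mask)
      comp <- composite_report(reg$series, pc1, n_boot = config$n_boot,
                               percentiles = config$percentiles,
                               seed = seed + 4L)
      list(regional = reg, composite = comp, n_pixels = sum(mask))
    }
  })

  tele <- stage("teleconnections", {
    idx <- if (synthetic) {
      drv <- attr(vintage, "drivers")
      generate_teleconnection_indices(min(monthly$year), max(monthly$year),
                                      coupling = 0.8, may_tx_z = drv$may,
                                      seed = seed + 5L)
    } else inputs$teleconnections
    if (is.null(idx)) NULL else {
      lapply(c(nao = "nao", ea = "ea", eawr = "eawr", scand = "scand"),
             function(cn) {
               df <- data.frame(year = idx$year, month = idx$month,
                                value = idx[[cn]])
               composite_report(df, pc1, n_boot = config$n_boot,
                                percentiles = config$percentiles,
                                seed = seed + 6L)
             })
    }
  })

  sst_map <- stage("sst", {
    sst <- if (synthetic) {
      z <- as.numeric(scale(pc1$value))
      generate_sst_field(sst_gen_config(),
                         data.frame(year = pc1$year, value = z),
                         seed = seed + 7L)
    } else inputs$sst
    if (is.null(sst)) NULL else {
      seas <- seasonal_sst_mean(sst)
      idx <- pc1$value[match(seas$year, pc1$year)]
      correlation_map(idx, seas, detrend = TRUE, alpha = config$alpha)
    }
  })

  manifest <- list(
    package = "vinoclim",
    version = as.character(utils::packageVersion("vinoclim")),
    seed = seed, synthetic = synthetic,
    config = unclass(config)[setdiff(names(unclass(config)), "seed")],
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  bundle <- list(bioclim = bioclim, pca = pca, trends = trends,
                 partial_correlations = pcor, kruskal_wallis = kw,
                 composites = composites, lai = lai,
                 teleconnections = tele, sst_map = sst_map,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(bioclim, file.path(out_dir, "bioclim.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(variable = rownames(pca$loadings),
                           as.data.frame(pca$loadings)),
                     file.path(out_dir, "pca_loadings.csv"),
                     row.names = FALSE)
    utils::write.csv(pca$scores, file.path(out_dir, "pca_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(pcor, file.path(out_dir, "partial_correlations.csv"),
                     row.names = FALSE)
    for (v in names(composites))
      utils::write.csv(composites[[v]],
                       file.path(out_dir, paste0("composite_", v, ".csv")),
                       row.names = FALSE)
    if (!is.null(lai))
      utils::write.csv(lai$composite,
                       file.path(out_dir, "composite_lai.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  bundle
}
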