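#' Integer percent difference between two mortality estimates
#'
#' `100 * (z_a - z_ref) / z_ref`, rounded half away from zero to the nearest
#' integer — the convention used when reporting, e.g., that open-access
#' mortality was 92% above the no-take reference.
#'
#' @param z_a Mortality of interest (1/yr).
#' @param z_ref Reference mortality (1/yr, > 0).
#' @return Integer percent difference (vectorised).
#' @examples
#' percent_difference(1.88, 0.98)
#' @export
percent_difference <- function(z_a, z_ref) {
  stopifnot(is.numeric(z_a), is.numeric(z_ref))
  if (any(z_ref <= 0)) stop("reference mortality must be positive",
                            call. = FALSE)
  x <- 100 * (z_a - z_ref) / z_ref
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Decompose total mortality against a no-take reference
#'
#' Splits a total-mortality estimate into the natural-mortality proxy
#' measured in the no-take area and the fishing-mortality remainder,
#' `F = Z - M`. A negative remainder is reported and flagged
#' (`below_reference`), never clamped: it is diagnostic of reference error
#' or sampling noise. For a species whose extraction is banned in the
#' stratum, a positive remainder is the signal of illegal fishing.
#'
#' @param fit Total-mortality estimate: a `catch_curve` fit or a number.
#' @param nt_fit No-take reference: a `catch_curve` fit or a number.
#' @return List with `z`, `m_ref`, `f_est` (`z - m_ref`, exactly),
#'   `pct_vs_ref` (integer %), `below_reference` (logical).
#' @examples
#' decompose_mortality(1.88, 0.98)
#' @export
decompose_mortality <- function(fit, nt_fit) {
  z <- if (inherits(fit, "catch_curve")) fit$z else fit
  m <- if (inherits(nt_fit, "catch_curve")) nt_fit$z else nt_fit
  stopifnot(is.numeric(z), is.numeric(m), length(z) == 1L, length(m) == 1L)
  f <- z - m
  list(z = z, m_ref = m, f_est = f,
       pct_vs_ref = percent_difference(z, m),
       below_reference = f < 0)
}

#' Default analysis configuration
#'
#' Central collection of the tunable analysis settings: age class width
#' (yr), zero-gap truncation length, spline options, over-asymptote policy,
#' the minimum stratum sample size below which a stratum is excluded (the
#' bootstrap-derived n = 200), the snapshot year of the cross-regime survey,
#' post-hoc adjustment, open-access equalization, and per-species growth
#' parameters with the extraction-ban flag. Growth coefficients K are the
#' published values for the two taxa; asymptotic lengths and t0 are
#' documented placeholders that real analyses must supply from regional
#' growth studies.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(class_width = 0.2,
       gap = 4L,
       spline_scale = "counts",
       spar = NULL,
       over_linf = "drop",
       min_n = 200L,
       snapshot_year = 2013L,
       posthoc_adjust = "none",
       equalize_oaa = TRUE,
       subsample_seed = 1L,
       species = list(
         loco = list(linf_mm = 150, k_per_yr = 0.433, t0_yr = 0,
                     banned_in_oaa = TRUE),
         limpet = list(linf_mm = 110, k_per_yr = 0.160, t0_yr = 0,
                       banned_in_oaa = FALSE)))
}

#' Read a pipeline configuration file
#'
#' Reads a YAML configuration and merges it over [default_config()], so a
#' file needs to state only the settings it changes.
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' Read a length-record CSV
#'
#' Expects the standard record layout: one row per measured individual with
#' columns `species`, `site`, `regime` (NT, MA or OAA), `ma_id` (empty
#' outside co-managed areas), `fishing_ground`, `year`, `length_mm`.
#'
#' @param path Path to a UTF-8 CSV with a header row.
#' @return Validated data frame of length records.
#' @export
read_length_records <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_length_records(d)
}

validate_length_records <- function(d) {
  need <- c("species", "site", "regime", "ma_id", "fishing_ground",
            "year", "length_mm")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing record columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!d$regime %in% c("NT", "MA", "OAA"))) {
    stop("regime must be one of NT, MA, OAA", call. = FALSE)
  }
  if (any(!is.finite(d$length_mm)) || any(d$length_mm <= 0)) {
    stop("length_mm must be positive", call. = FALSE)
  }
  if (any(d$regime == "NT" & !is.na(d$ma_id) & d$ma_id != "")) {
    stop("no-take records cannot carry a management-area id", call. = FALSE)
  }
  d
}

species_growth <- function(config, sp) {
  s <- config$species[[sp]]
  if (is.null(s)) stop(sprintf("no growth parameters configured for '%s'", sp),
                       call. = FALSE)
  growth_params(s$linf_mm, s$k_per_yr, s$t0_yr)
}

fit_group <- function(records, gp, config) {
  catch_curve(records$length_mm, gp,
              class_width = config$class_width, gap = config$gap,
              spline_scale = config$spline_scale, spar = config$spar,
              over_linf = config$over_linf)
}

#' Tabulate a named list of catch-curve fits
#'
#' @param fits Named list of `catch_curve` objects.
#' @return Data frame with one row per fit: `group`, `z`, `se_z`, `ci_lo`,
#'   `ci_hi`, `r2`, `recruit_age`, `n_classes`, `n_records`, `n_dropped`.
#' @export
fit_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(group = nm, z = f$z, se_z = f$se_z,
               ci_lo = f$ci95[1], ci_hi = f$ci95[2], r2 = f$r2,
               recruit_age = f$recruit_age, n_classes = f$n_classes,
               n_records = f$n_records, n_dropped = f$n_dropped)
  }))
}

# Drop strata below the minimum reliable sample size, with a log note.
apply_min_n <- function(records, strata, min_n, quiet = FALSE) {
  n_by <- table(strata)
  small <- names(n_by)[n_by < min_n]
  if (length(small)) {
    if (!quiet) {
      message("dropping strata below the minimum sample size (",
              min_n, "): ", paste(small, collapse = ", "))
    }
    records <- records[!strata %in% small, , drop = FALSE]
  }
  records
}

#' Regional analysis: mortality across management regimes
#'
#' The cross-regime comparison for one species at the snapshot year: strata
#' below the minimum sample size are excluded; open-access strata from
#' different sites are equalized by frequency-matched subsampling of the
#' larger strata down to the smallest (each matched to its own age
#' distribution); records are then pooled per regime, a catch curve is
#' fitted per regime, and the regime slopes are compared by one-way ANCOVA
#' with pairwise post-hoc contrasts. Each exploited regime is decomposed
#' against the no-take reference, and for a species banned from open-access
#' extraction a positive open-access fishing-mortality remainder is flagged
#' as inferred illegal fishing.
#'
#' @param records Length-record data frame (see [read_length_records()]).
#' @param config Configuration list, see [default_config()].
#' @param species Species to analyse; default all in `records`.
#' @return Named list (per species) of reports: `fits` (table),
#'   `comparison`, `posthoc`, `decomposition`, `illegal_fishing_inferred`.
#' @export
run_regional <- function(records, config = default_config(), species = NULL) {
  records <- validate_length_records(records)
  if (is.null(species)) species <- unique(records$species)
  out <- lapply(species, function(sp) {
    d <- records[records$species == sp & records$year == config$snapshot_year, ]
    if (!all(c("NT", "MA", "OAA") %in% d$regime)) {
      stop(sprintf("species '%s': all three regimes required at year %d",
                   sp, config$snapshot_year), call. = FALSE)
    }
    gp <- species_growth(config, sp)
    strata <- paste(d$site, d$regime)
    d <- apply_min_n(d, strata, config$min_n)
    if (isTRUE(config$equalize_oaa)) {
      oaa <- d[d$regime == "OAA", ]
      sites <- unique(oaa$site)
      if (length(sites) > 1L) {
        n_target <- min(table(oaa$site))
        eq <- do.call(rbind, lapply(seq_along(sites), function(i) {
          s <- oaa[oaa$site == sites[i], ]
          if (nrow(s) > n_target) {
            frequency_matched_subsample(s, n_target, gp,
                                        class_width = config$class_width,
                                        seed = config$subsample_seed + i,
                                        over_linf = config$over_linf)
          } else s
        }))
        d <- rbind(d[d$regime != "OAA", ], eq)
      }
    }
    fits <- lapply(c(NT = "NT", MA = "MA", OAA = "OAA"), function(rg) {
      fit_group(d[d$regime == rg, ], gp, config)
    })
    cmp <- ancova_slopes(fits, design = "regime")
    ph <- posthoc_pairs(cmp, adjust = config$posthoc_adjust)
    dec <- lapply(c(MA = "MA", OAA = "OAA"), function(rg) {
      decompose_mortality(fits[[rg]], fits$NT)
    })
    banned <- isTRUE(config$species[[sp]]$banned_in_oaa)
    list(species = sp,
         fits = fit_table(fits),
         comparison = cmp,
         posthoc = ph,
         decomposition = dec,
         illegal_fishing_inferred = banned && dec$OAA$f_est > 0)
  })
  names(out) <- species
  out
}

#' Local analysis: regimes within and across sites
#'
#' Pools records per (site, regime) cell for sites holding both co-managed
#' and open-access grounds and tests slope homogeneity across cells with the
#' nested ANCOVA; then, within each site, compares the individual co-managed
#' areas against the pooled open-access stratum by one-way ANCOVA. With a
#' single eligible site the nested test is skipped (reported as an error
#' message) while the within-site analyses still run.
#'
#' @inheritParams run_regional
#' @return Named list (per species) with `nested` (a `slope_comparison` or
#'   an error message) and `within_site` (per-site comparison + post-hoc).
#' @export
run_local <- function(records, config = default_config(), species = NULL) {
  records <- validate_length_records(records)
  if (is.null(species)) species <- unique(records$species)
  out <- lapply(species, function(sp) {
    d <- records[records$species == sp & records$year == config$snapshot_year &
                   records$regime %in% c("MA", "OAA"), ]
    gp <- species_growth(config, sp)
    d <- apply_min_n(d, paste(d$site, d$regime), config$min_n)
    has_both <- vapply(split(d$regime, d$site),
                       function(r) all(c("MA", "OAA") %in% r), logical(1))
    sites <- names(has_both)[has_both]
    if (length(sites) == 0L) stop("no site holds both MA and OAA records",
                                  call. = FALSE)
    d <- d[d$site %in% sites, ]
    cell_keys <- expand.grid(site = sites, regime = c("MA", "OAA"),
                             stringsAsFactors = FALSE)
    nested <- tryCatch({
      if (length(sites) < 2L) stop("nested test needs at least 2 sites",
                                   call. = FALSE)
      fits <- lapply(seq_len(nrow(cell_keys)), function(i) {
        fit_group(d[d$site == cell_keys$site[i] &
                      d$regime == cell_keys$regime[i], ], gp, config)
      })
      nested_ancova(fits, cell_keys$site, cell_keys$regime)
    }, error = function(e) conditionMessage(e))
    within_site <- lapply(stats::setNames(sites, sites), function(s) {
      ds <- d[d$site == s, ]
      mas <- sort(unique(ds$ma_id[ds$regime == "MA"]))
      fits <- c(lapply(stats::setNames(mas, paste0("MA_", mas)), function(ma) {
        fit_group(ds[ds$regime == "MA" & ds$ma_id == ma, ], gp, config)
      }), list(OAA = fit_group(ds[ds$regime == "OAA", ], gp, config)))
      cmp <- ancova_slopes(fits, design = "ma-vs-oaa")
      list(comparison = cmp,
           posthoc = posthoc_pairs(cmp, adjust = config$posthoc_adjust),
           fits = fit_table(fits))
    })
    list(species = sp, nested = nested, within_site = within_site)
  })
  names(out) <- species
  out
}

#' Temporal analysis: annual mortality in co-managed areas
#'
#' Fits one catch curve per management area and year, tests the regional
#' temporal trend of the annual Z estimates (single-df year regression),
#' runs the per-area across-year ANCOVA with post-hoc year contrasts, and,
#' when two species are present, compares their annual Z estimates with the
#' pooled-variance t-test.
#'
#' @inheritParams run_regional
#' @param min_years Minimum number of years of co-managed data required.
#' @return Named list (per species) with `z_table` (`ma`, `year`, `z`, ...),
#'   `trend`, `per_ma` (ANCOVA + post-hoc per area), plus a top-level
#'   `species_test` when two species are available.
#' @export
run_temporal <- function(records, config = default_config(), species = NULL,
                         min_years = 3L) {
  records <- validate_length_records(records)
  if (is.null(species)) species <- unique(records$species)
  out <- lapply(species, function(sp) {
    d <- records[records$species == sp & records$regime == "MA", ]
    if (length(unique(d$year)) < min_years) {
      stop(sprintf("species '%s': need co-managed data from at least %d years",
                   sp, min_years), call. = FALSE)
    }
    gp <- species_growth(config, sp)
    d$ma <- paste(d$site, d$ma_id)
    cells <- unique(d[, c("ma", "year")])
    cells <- cells[order(cells$ma, cells$year), ]
    fits <- vector("list", nrow(cells))
    names(fits) <- paste(cells$ma, cells$year, sep = ":")
    for (i in seq_len(nrow(cells))) {
      fits[[i]] <- fit_group(d[d$ma == cells$ma[i] & d$year == cells$year[i], ],
                             gp, config)
    }
    z_table <- cbind(cells, fit_table(fits)[, -1], row.names = NULL)
    per_ma <- lapply(stats::setNames(unique(cells$ma), unique(cells$ma)),
                     function(ma) {
      yrs <- cells$year[cells$ma == ma]
      if (length(yrs) < 2L) return(NULL)
      yfits <- fits[paste(ma, yrs, sep = ":")]
      names(yfits) <- as.character(yrs)
      cmp <- ancova_slopes(yfits, design = "year")
      list(comparison = cmp,
           posthoc = posthoc_pairs(cmp, adjust = config$posthoc_adjust))
    })
    list(species = sp, z_table = z_table,
         trend = temporal_trend(z_table$z, z_table$year),
         per_ma = per_ma)
  })
  names(out) <- species
  if (length(species) >= 2L) {
    out$species_test <- species_ttest(out[[species[1]]]$z_table$z,
                                      out[[species[2]]]$z_table$z)
  }
  out
}

#' Write pipeline reports to CSV and JSON
#'
#' Serializes the group-fit tables, the comparison statistics and the
#' mortality decompositions of a [run_regional()] report to `fits.csv`,
#' `comparisons.csv`, `decomposition.csv` and a mirroring `report.json`
#' under `dir`.
#'
#' @param report A [run_regional()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of file paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fits <- do.call(rbind, lapply(report, function(r) {
    cbind(species = r$species, r$fits)
  }))
  comps <- do.call(rbind, lapply(report, function(r) {
    rbind(data.frame(species = r$species, design = r$comparison$design,
                     term = "interaction", f_stat = r$comparison$f_stat,
                     df_num = r$comparison$df_num,
                     df_den = r$comparison$df_den, p = r$comparison$p),
          data.frame(species = r$species, design = r$comparison$design,
                     term = paste(r$posthoc$level_1, "vs", r$posthoc$level_2),
                     f_stat = r$posthoc$f_stat, df_num = r$posthoc$df_num,
                     df_den = r$posthoc$df_den, p = r$posthoc$p))
  }))
  dec <- do.call(rbind, lapply(report, function(r) {
    do.call(rbind, lapply(names(r$decomposition), function(rg) {
      x <- r$decomposition[[rg]]
      data.frame(species = r$species, regime = rg, z = x$z, m_ref = x$m_ref,
                 f_est = x$f_est, pct_vs_ref = x$pct_vs_ref,
                 below_reference = x$below_reference)
    }))
  }))
  paths <- file.path(dir, c("fits.csv", "comparisons.csv",
                            "decomposition.csv", "report.json"))
  utils::write.csv(fits, paths[1], row.names = FALSE)
  utils::write.csv(comps, paths[2], row.names = FALSE)
  utils::write.csv(dec, paths[3], row.names = FALSE)
  jsonlite::write_json(list(fits = fits, comparisons = comps,
                            decomposition = dec),
                       paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
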