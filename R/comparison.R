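# Is a numeric vector z-normalized (population convention)?
looks_normalized <- function(v) {
  abs(mean(v)) < 1e-8 && abs(sqrt(mean((v - mean(v))^2)) - 1) < 1e-6
}

#' Pair a conservation profile with a structural profile
#'
#' Joins the two normalized profiles through a [site map][map_to_structure]
#' into the common residue set, in structure order: `x` holds the
#' conservation z-scores, `y` the structural z-scores (z_w or z_r).
#'
#' @param cons a normalized conservation profile (see
#'   [normalize_conservation()]).
#' @param struct a normalized structural profile (see
#'   [normalize_profile()]).
#' @param sitemap the site map linking them.
#' @return a `profile_pair` tibble with columns subunit, seq_num, icode,
#'   x (conservation z), y (structural z).
#' @export
pair_profiles <- function(cons, struct, sitemap) {
  if (!isTRUE(attr(cons, "normalized")) && !looks_normalized(cons$score)) {
    abort("conservation profile is not normalized; call normalize_conservation()",
          class = "capsidprof_input_error")
  }
  if (!identical(attr(struct, "kind"), "normalized") &&
      !looks_normalized(struct$value)) {
    abort("structural profile is not normalized; call normalize_profile()",
          class = "capsidprof_input_error")
  }
  pr <- sitemap$pairs
  skey <- paste(struct$subunit, struct$seq_num, struct$icode, sep = "\r")
  pkey <- paste(pr$subunit, pr$seq_num, pr$icode, sep = "\r")
  hit_pair <- match(skey, pkey)            # structure order
  in_map <- which(!is.na(hit_pair))
  pr <- pr[hit_pair[in_map], ]
  hit_cons <- match(pr$pos, cons$pos)
  ok <- !is.na(hit_cons)
  pair <- tibble(subunit = pr$subunit[ok], seq_num = pr$seq_num[ok],
                 icode = pr$icode[ok],
                 x = cons$score[hit_cons[ok]],
                 y = struct$value[in_map][ok])
  if (nrow(pair) < 3) {
    abort(paste0("insufficient overlap between profiles: ", nrow(pair),
                 " paired residue(s), need >= 3"),
          class = "capsidprof_input_error")
  }
  structure(pair, class = c("profile_pair", class(as_tibble(pair))))
}

#' Pearson correlation of a profile pair
#'
#' The product-moment correlation between the conservation z-scores and
#' the structural z-scores. Under the package-wide orientation (low
#' score = conserved; low z_w = densely packed; low z_r = near the
#' centroid), agreement between conservation and either structural model
#' appears as a positive r.
#'
#' @param pair a [profile pair][pair_profiles].
#' @return correlation coefficient in \[-1, 1\].
#' @export
profile_pearson <- function(pair) {
  if (nrow(pair) < 3) {
    abort("need at least 3 paired residues for a correlation",
          class = "capsidprof_input_error")
  }
  if (sd(pair$x) == 0 || sd(pair$y) == 0) {
    abort("constant profile: correlation undefined",
          class = "capsidprof_degenerate_error")
  }
  cor(pair$x, pair$y)
}

#' Binned conservation trend
#'
#' Bins the conservation z-scores into half-open intervals
#' `[k*w, (k+1)*w)` anchored at 0 (default width 0.3 z units), averages
#' the structural z-scores over the residues of each bin, and fits an
#' ordinary least-squares line through the (bin center, bin mean) points
#' of the occupied bins. A high fit r-squared says the structural model
#' tracks conservation linearly across its whole range; departures (a
#' plateau at one end, say) show up as a depressed r-squared.
#'
#' @param pair a [profile pair][pair_profiles].
#' @param bin_width bin width in z units (default 0.3).
#' @param min_count minimal occupancy for a bin to enter the fit
#'   (default 1).
#' @return a `binned_trend`: list with `bins` (k, center, mean_y, count),
#'   `fit` (slope, intercept, r_squared; `NULL` when fewer than 2 bins
#'   qualify), `bin_width` and `n`.
#' @export
binned_trend <- function(pair, bin_width = 0.3, min_count = 1) {
  if (nrow(pair) < 3) {
    abort("need at least 3 paired residues", class = "capsidprof_input_error")
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    abort("`bin_width` must be positive", class = "capsidprof_input_error")
  }
  k <- floor(pair$x / bin_width)
  bins <- tibble(k = k, y = pair$y) |>
    group_by(.data$k) |>
    summarise(mean_y = mean(.data$y), count = n(), .groups = "drop") |>
    mutate(center = (.data$k + 0.5) * bin_width) |>
    select("k", "center", "mean_y", "count") |>
    arrange(.data$k)
  usable <- bins[bins$count >= min_count, ]
  fit <- NULL
  if (nrow(usable) >= 2) {
    lmfit <- lm(mean_y ~ center, data = usable)
    ss_tot <- sum((usable$mean_y - mean(usable$mean_y))^2)
    fit <- list(slope = unname(coef(lmfit)[2]),
                intercept = unname(coef(lmfit)[1]),
                r_squared = if (ss_tot > 0)
                  1 - sum(stats::resid(lmfit)^2) / ss_tot else NA_real_)
  }
  structure(list(bins = bins, fit = fit, bin_width = bin_width,
                 n = nrow(pair)),
            class = "binned_trend")
}

#' @export
print.binned_trend <- function(x, ...) {
  cat(sprintf("<binned_trend> %d bins (width %.3g) over %d residues\n",
              nrow(x$bins), x$bin_width, x$n))
  if (is.null(x$fit)) {
    cat("  no fit (fewer than 2 usable bins)\n")
  } else {
    cat(sprintf("  fit: slope %.4f, intercept %.4f, r^2 %.4f\n",
                x$fit$slope, x$fit$intercept, x$fit$r_squared))
  }
  invisible(x)
}

#' Pool profile pairs across structures
#'
#' Concatenates normalized profile pairs from several capsids, for
#' dataset-level trend analyses that average over structures.
#'
#' @param pairs list of [profile pairs][pair_profiles].
#' @return one `profile_pair` tibble.
#' @export
pool_pairs <- function(pairs) {
  out <- bind_rows(lapply(pairs, as_tibble))
  if (nrow(out) == 0) {
    abort("nothing to pool", class = "capsidprof_input_error")
  }
  structure(out, class = c("profile_pair", class(as_tibble(out))))
}

#' Compare one capsid structure with a conservation profile
#'
#' The per-structure pipeline: read (and optionally expand) the
#' structure, compute the requested structural profile of one subunit in
#' the context of the whole model, z-normalize it; smooth and z-normalize
#' the conservation profile; map sites onto residues; pair; correlate.
#'
#' @param structure path to a PDB/mmCIF file, or a C-alpha model.
#' @param conservation path to a Rate4Site/ConSurf grades file, or a
#'   conservation profile tibble.
#' @param subunit subunit id whose profile is reported.
#' @param model `"wcn"` or `"cdist"`.
#' @param assembly passed to [read_structure()].
#' @param transforms passed to [read_structure()].
#' @param smooth_window sliding-window width for the conservation profile
#'   (odd; 1 disables smoothing). Default 5.
#' @param offset,max_mismatch,force passed to [map_to_structure()].
#' @return a `capsid_comparison`: list with `r`, `n`, `pair`, `sitemap`,
#'   `model`, `subunit` and the normalized profiles.
#' @export
compare_capsid <- function(structure, conservation, subunit,
                           model = c("wcn", "cdist"), assembly = "asu",
                           transforms = NULL, smooth_window = 5,
                           offset = 0, max_mismatch = 0.05, force = FALSE) {
  model <- match.arg(model)
  mod <- if (is_calpha_model(structure)) structure
         else read_structure(structure, assembly = assembly,
                             transforms = transforms)
  cons <- if (is.character(conservation)) parse_rate4site(conservation)
          else conservation
  prof <- if (model == "wcn") wcn_profile(mod, subunit)
          else cdistance_profile(mod, subunit)
  zprof <- normalize_profile(prof)
  sc <- if (smooth_window > 1) smooth_profile(cons, smooth_window) else cons
  zsc <- normalize_conservation(sc)
  sm <- map_to_structure(cons, mod, subunit, offset = offset,
                         max_mismatch = max_mismatch, force = force)
  pair <- pair_profiles(zsc, zprof, sm)
  structure(list(r = profile_pearson(pair), n = nrow(pair), pair = pair,
                 sitemap = sm, model = model, subunit = subunit,
                 structural = zprof, conservation = zsc),
            class = "capsid_comparison")
}

#' @export
print.capsid_comparison <- function(x, ...) {
  cat(sprintf("<capsid_comparison> model=%s subunit=%s: Pearson r = %.6f over %d residues\n",
              x$model, x$subunit, x$r, x$n))
  invisible(x)
}

#' Batch comparison over many capsids
#'
#' Runs [compare_capsid()] for every row of a job table and aggregates
#' the per-structure Pearson correlations into per-model averages.
#' Individual failures are recorded, not fatal to the batch.
#'
#' @param jobs a data frame with columns `structure`, `conservation`,
#'   `subunit`, and optionally `model` (default "wcn"), `assembly`
#'   ("asu"), `smooth_window` (5) and `offset` (0). A `structure_id`
#'   column names rows in the output (defaults to the structure path).
#' @param keep_pairs also return the profile pairs (for pooled trend
#'   analysis). Default FALSE.
#' @return a `batch_summary`: list with `per_structure`, `averages`,
#'   `failures` and (optionally) `pairs`.
#' @export
batch_compare <- function(jobs, keep_pairs = FALSE) {
  jobs <- as_tibble(jobs)
  need <- c("structure", "conservation", "subunit")
  if (!all(need %in% names(jobs)) || nrow(jobs) == 0) {
    abort("jobs needs >= 1 row and columns structure, conservation, subunit",
          class = "capsidprof_input_error")
  }
  if (!"model" %in% names(jobs)) jobs$model <- "wcn"
  if (!"assembly" %in% names(jobs)) jobs$assembly <- "asu"
  if (!"smooth_window" %in% names(jobs)) jobs$smooth_window <- 5
  if (!"offset" %in% names(jobs)) jobs$offset <- 0
  if (!"structure_id" %in% names(jobs)) {
    jobs$structure_id <- vapply(jobs$structure, function(s)
      if (is.character(s)) s else "in-memory model", "")
  }

  res <- purrr::map(seq_len(nrow(jobs)), function(i) {
    j <- jobs[i, ]
    tryCatch({
      cmp <- compare_capsid(
        structure = if (is.list(j$structure)) j$structure[[1]] else j$structure,
        conservation = if (is.list(j$conservation)) j$conservation[[1]]
                       else j$conservation,
        subunit = j$subunit, model = j$model, assembly = j$assembly,
        smooth_window = j$smooth_window, offset = j$offset)
      list(ok = TRUE,
           row = tibble(structure_id = j$structure_id, subunit = j$subunit,
                        model = j$model, r = cmp$r, n = cmp$n),
           pair = cmp$pair)
    }, error = function(e) {
      list(ok = FALSE,
           fail = tibble(structure_id = j$structure_id, subunit = j$subunit,
                         model = j$model, error = conditionMessage(e)))
    })
  })

  per <- bind_rows(purrr::map(res[purrr::map_lgl(res, "ok")], "row"))
  fails <- bind_rows(purrr::map(res[!purrr::map_lgl(res, "ok")], "fail"))
  if (nrow(per) == 0) {
    abort(paste0("all ", nrow(jobs), " jobs failed; first error: ",
                 fails$error[1]),
          class = "capsidprof_batch_error")
  }
  averages <- per |>
    group_by(.data$model) |>
    summarise(mean_r = mean(.data$r), n_structures = n(), .groups = "drop")
  out <- list(per_structure = per, averages = averages, failures = fails)
  if (keep_pairs) {
    out$pairs <- purrr::map(res[purrr::map_lgl(res, "ok")], "pair")
  }
  structure(out, class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf("<batch_summary> %d structure(s), %d failure(s)\n",
              nrow(x$per_structure), nrow(x$failures)))
  for (i in seq_len(nrow(x$averages))) {
    cat(sprintf("  %s: mean r = %.4f over %d structures\n",
                x$averages$model[i], x$averages$mean_r[i],
                x$averages$n_structures[i]))
  }
  invisible(x)
}
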