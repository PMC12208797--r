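#' Process one recording into a representative ensemble beat
#'
#' Runs the standard per-recording chain: Savitzky-Golay smoothing of the
#' Doppler velocity (order 2, window 11) on its native grid, upsampling of
#' velocity to the pressure grid, beat detection at the diastolic pressure
#' foot, and ensemble averaging of the accepted beats.
#'
#' @param rec a \code{\link{vessel_recording}}.
#' @param beats optional \code{\link{beat_index}} (e.g. known onsets);
#'   detected automatically when omitted.
#' @param window optional analysis window \code{c(start, end)} in seconds.
#' @param min_beats minimum accepted beats for the ensemble (default 8).
#' @return An \code{\link{ensemble_beat}}.
#' @export
analyze_recording <- function(rec, beats = NULL, window = NULL,
                              min_beats = 8L) {
  rec$u <- smooth_velocity(rec$u, rec$fs_velocity)
  rec <- resample_to_common_grid(rec)
  if (is.null(beats)) beats <- detect_beats(rec$pa, rec$fs_pressure)
  ensemble_average(rec, beats, window, min_beats = min_beats)
}

#' Full per-vessel analysis across conditions and phases
#'
#' Computes the conventional indices (per phase) and the wave-intensity
#' peak sets (per condition x phase) of one vessel from its four recordings,
#' and stratifies the vessel from the post-PCI indices.
#'
#' @param pre_rest,pre_hyp,post_rest,post_hyp \code{\link{vessel_recording}}s.
#' @param vessel_id identifier; defaults to the one carried by the
#'   recordings.
#' @param metadata free-form list (e.g. diameter stenosis).
#' @return An object of class \code{vessel_result} with elements \code{pre},
#'   \code{post} (\code{\link{hemo_indices}}), \code{wia} (named list of
#'   \code{wave_peaks} for \code{pre_rest}, \code{pre_hyp},
#'   \code{post_rest}, \code{post_hyp}; \code{NULL} with a note when a
#'   suction wave could not be identified) and \code{group}.
#' @export
analyze_vessel <- function(pre_rest, pre_hyp, post_rest, post_hyp,
                           vessel_id = pre_rest$vessel_id,
                           metadata = list()) {
  recs <- list(pre_rest = pre_rest, pre_hyp = pre_hyp,
               post_rest = post_rest, post_hyp = post_hyp)
  ebs <- lapply(recs, analyze_recording)
  ind_pre <- compute_indices(ebs$pre_rest, ebs$pre_hyp, vessel_id, "pre")
  ind_post <- compute_indices(ebs$post_rest, ebs$post_hyp, vessel_id, "post")
  notes <- character(0)
  wia <- lapply(names(ebs), function(nm) {
    tryCatch(extract_peaks(net_wave_intensity(ebs[[nm]])),
             corowia_missing_wave = function(e) {
               notes <<- c(notes, sprintf("%s: %s", nm, conditionMessage(e)))
               NULL
             })
  })
  names(wia) <- names(ebs)
  structure(list(
    vessel_id = vessel_id,
    pre = ind_pre, post = ind_post,
    wia = wia,
    group = classify_vessel(ind_post),
    metadata = metadata, notes = notes
  ), class = "vessel_result")
}

#' @export
print.vessel_result <- function(x, ...) {
  cat(sprintf("<vessel_result> %s  group: %s\n", x$vessel_id, x$group))
  cat(sprintf("  pre : FFR %.3f  CFVR %.2f  hSR %.3f\n",
              x$pre$FFR, x$pre$CFVR, x$pre$hSR))
  cat(sprintf("  post: FFR %.3f  CFVR %.2f  hSR %.3f\n",
              x$post$FFR, x$post$CFVR, x$post$hSR))
  if (!is.null(x$wia$post_hyp))
    cat(sprintf("  post-PCI hyperemic BEW %.2f (10 kW.m-2.s-2), tBEW %.2f\n",
                x$wia$post_hyp$BEW_peak, x$wia$post_hyp$tBEW_peak))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

index_matrix <- function(results, phase) {
  vars <- c("FFR", "CFVR", "hSR", "deltaP", "bMR", "hMR", "bAPV", "hAPV",
            "MRR", "RRR")
  out <- sapply(vars, function(v)
    vapply(results, function(r) r[[phase]][[v]], numeric(1)))
  out <- matrix(out, nrow = length(results),
                dimnames = list(vapply(results, `[[`, "", "vessel_id"), vars))
  out
}

peak_value <- function(r, cell, var) {
  w <- r$wia[[cell]]
  if (is.null(w)) return(NA_real_)
  if (var == "tBEW") w$tBEW_peak else w[[paste0(var, "_peak")]]
}

#' Build the study-level report tables
#'
#' Reproduces the standard structure of a peri-PCI physiology study on a
#' list of analysed vessels:
#' \itemize{
#'  \item \code{paired}: pre- vs post-PCI comparison of FFR, CFVR, hSR,
#'    bMR, hMR, bAPV and hAPV over all vessels (paired tests).
#'  \item \code{groups}: concordant vs discordant (residual low FFR despite
#'    normal hSR) lesion-level comparison of the pre- and post-PCI indices
#'    including MRR and RRR.
#'  \item \code{wia}: rest/hyperemia x pre/post group comparison of the
#'    four wave peaks and tBEW_peak.
#'  \item \code{correlations}: hyperemic post-PCI deltaP vs Pd/Pa and
#'    deltaP vs hAPV across vessels.
#' }
#' Group tables are flagged not-computable (with the run continuing) when a
#' compared group has fewer than 2 vessels. Output is a pure function of the
#' input set: vessels are ordered by id internally. Reported p-values are
#' raw (no multiple-testing correction), as is conventional for exploratory
#' physiology cohorts; the report notes this.
#'
#' @param results list of \code{\link{vessel_result}} objects.
#' @return An object of class \code{cohort_report} whose elements are data
#'   frames (or \code{NULL} with an explanatory note).
#' @export
build_tables <- function(results) {
  stopifnot(length(results) >= 2L,
            all(vapply(results, inherits, TRUE, "vessel_result")))
  results <- results[order(vapply(results, `[[`, "", "vessel_id"))]
  notes <- c("p-values are raw (no multiple-testing correction)")

  pre <- index_matrix(results, "pre")
  post <- index_matrix(results, "post")

  paired_vars <- c("FFR", "CFVR", "hSR", "bMR", "hMR", "bAPV", "hAPV")
  paired <- do.call(rbind, lapply(paired_vars, function(v)
    as.data.frame(compare_paired(pre[, v], post[, v], variable = v))))

  grp <- vapply(results, `[[`, "", "group")
  conc <- grp == "concordant"; disc <- grp == "discordant"
  groups_tab <- NULL
  wia_tab <- NULL
  if (sum(conc) >= 2L && sum(disc) >= 2L) {
    gvars <- c("FFR", "CFVR", "hSR", "bMR", "hMR", "bAPV", "hAPV", "MRR", "RRR")
    rows <- list()
    for (ph in c("pre", "post")) {
      m <- if (ph == "pre") pre else post
      for (v in gvars) {
        row <- as.data.frame(compare_independent(
          m[conc, v], m[disc, v], variable = sprintf("%s_%s", v, ph)))
        rows[[length(rows) + 1L]] <- row
      }
    }
    groups_tab <- do.call(rbind, rows)

    wvars <- c("FCW", "BCW", "FEW", "BEW", "tBEW")
    rows <- list()
    for (cond in c("rest", "hyp")) for (ph in c("pre", "post")) {
      cell <- paste0(ph, "_", cond)
      for (v in wvars) {
        xc <- vapply(results[conc], peak_value, numeric(1), cell, v)
        xd <- vapply(results[disc], peak_value, numeric(1), cell, v)
        if (sum(is.finite(xc)) >= 3L && sum(is.finite(xd)) >= 3L) {
          row <- as.data.frame(compare_independent(
            xc, xd, variable = sprintf("%s_%s_%s", v, cond, ph)))
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
    wia_tab <- do.call(rbind, rows)
  } else {
    notes <- c(notes, sprintf(
      "group comparison not computable: %d concordant, %d discordant vessels",
      sum(conc), sum(disc)))
  }

  cors <- NULL
  ok <- is.finite(post[, "deltaP"])
  if (sum(ok) >= 3L) {
    ratio <- post[, "FFR"]
    c1 <- correlate(post[ok, "deltaP"], ratio[ok])
    c2 <- correlate(post[ok, "deltaP"], post[ok, "hAPV"])
    cors <- data.frame(
      pair = c("deltaP vs Pd/Pa (post, hyperemia)",
               "deltaP vs hAPV (post, hyperemia)"),
      r = c(c1$coefficient, c2$coefficient),
      p = c(c1$p, c2$p),
      method = c(c1$method, c2$method),
      stringsAsFactors = FALSE
    )
  }

  structure(list(
    paired = paired, groups = groups_tab, wia = wia_tab,
    correlations = cors,
    n_vessels = length(results),
    group_sizes = c(concordant = sum(conc), discordant = sum(disc),
                    abnormal_hSR = sum(grp == "abnormal_hSR")),
    notes = notes
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat(sprintf("<cohort_report> %d vessels (%d concordant, %d discordant, %d abnormal hSR)\n",
              x$n_vessels, x$group_sizes["concordant"],
              x$group_sizes["discordant"], x$group_sizes["abnormal_hSR"]))
  show <- function(df, title) {
    cat("\n--", title, "--\n")
    if (is.null(df)) { cat("  not computable\n"); return(invisible()) }
    df[] <- lapply(df, function(c) if (is.numeric(c)) signif(c, digits) else c)
    print(df, row.names = FALSE)
  }
  show(x$paired, "paired pre/post comparison (all vessels)")
  show(x$groups, "concordant vs discordant indices")
  show(x$wia, "concordant vs discordant wave intensity")
  show(x$correlations, "pressure-drop correlations")
  if (length(x$notes)) cat("\nnotes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.cohort_report <- function(object, ...) print(object, ...)
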