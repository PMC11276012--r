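# Replica-level summary statistics: category fractions, contact-distance
# summaries, and between-ligand comparisons.

#' Category fractions per replica and pooled
#'
#' Fractions of frames in each of the three polar-contact categories, per
#' replica, plus a frame-count-weighted pooled triple. Each triple sums to
#' one exactly. (How published per-ligand percentages pool replicas is
#' often unstated; both views are reported so either convention can be
#' matched.)
#'
#' @param analyses list of `"contact_analysis"` objects (one per replica,
#'   same ligand/target configuration).
#' @return list of class `"category_fractions"`: data.frame `per_replica`
#'   (replica_id, n_frames, f_direct, f_water_only, f_none) and named
#'   vector `pooled`.
#' @export
category_fractions <- function(analyses) {
  if (inherits(analyses, "contact_analysis")) analyses <- list(analyses)
  if (length(analyses) == 0) stop("no category series supplied")
  rows <- lapply(analyses, function(an) {
    cats <- an$categories$category
    if (length(cats) == 0) stop("empty category series in replica ",
                                an$replica_id)
    n <- length(cats)
    data.frame(replica_id = an$replica_id, n_frames = n,
               f_direct = sum(cats == "DIRECT_INTERACTION") / n,
               f_water_only = sum(cats == "WATER_MEDIATED_ONLY") / n,
               f_none = sum(cats == "NO_POLAR_CONTACT") / n)
  })
  per <- do.call(rbind, rows)
  w <- per$n_frames / sum(per$n_frames)
  pooled <- c(f_direct = sum(w * per$f_direct),
              f_water_only = sum(w * per$f_water_only),
              f_none = sum(w * per$f_none))
  structure(list(per_replica = per, pooled = pooled),
            class = "category_fractions")
}

#' @export
print.category_fractions <- function(x, ...) {
  cat(sprintf(
    "pooled: %.1f%% direct, %.1f%% water-mediated-only, %.1f%% none (n=%d replicas)\n",
    100 * x$pooled["f_direct"], 100 * x$pooled["f_water_only"],
    100 * x$pooled["f_none"], nrow(x$per_replica)))
  invisible(x)
}

#' Average contact distance across replicas
#'
#' Each frame where the contact exists contributes its closest qualifying
#' pair distance (a charged group can bridge both carboxylate oxygens at
#' once; the contact distance is the near one). Frame values are averaged
#' per replica, then across replicas with SEM. Replicas with no
#' qualifying frames are excluded and listed.
#'
#' @param analyses list of `"contact_analysis"` objects.
#' @param type contact type to summarize (`"salt_bridge"` or `"hbond"`);
#'   rows of `analysis$direct` are filtered on it.
#' @return list of class `"distance_summary"`: `per_replica` data.frame
#'   (replica_id, n_frames, mean_A), `mean_A`, `sem_A`,
#'   `excluded_replicas`.
#' @export
distance_summary <- function(analyses, type = "salt_bridge") {
  if (inherits(analyses, "contact_analysis")) analyses <- list(analyses)
  rows <- list(); excluded <- integer(0)
  for (an in analyses) {
    d <- an$direct
    d <- d[d$type == type, , drop = FALSE]
    if (nrow(d) == 0) {
      excluded <- c(excluded, an$replica_id)
      next
    }
    per_frame <- tapply(d$distance_A, d$frame, min)
    rows[[length(rows) + 1]] <- data.frame(
      replica_id = an$replica_id, n_frames = length(per_frame),
      mean_A = mean(per_frame))
  }
  if (length(rows) == 0)
    stop("no qualifying frames for contact type '", type,
         "' in any replica")
  per <- do.call(rbind, rows)
  agg <- aggregate_replicas(per$mean_A)
  structure(list(per_replica = per, mean_A = agg$mean, sem_A = agg$sem,
                 excluded_replicas = excluded, type = type),
            class = "distance_summary")
}

#' Compare a per-replica statistic between two ligands
#'
#' Welch's unequal-variance two-sample t test on per-replica summaries
#' (fractions, correlation times, or mean distances), two-sided. Replicas
#' are the independent statistical unit. When both groups are constant the
#' test degenerates: equal means give statistic 0 and p = 1; unequal means
#' give an infinite statistic and p = 0.
#'
#' @param a,b numeric vectors of per-replica values (each n >= 2).
#' @return list of class `"comparison_result"`: `statistic`, `p_value`,
#'   `test_name`, `df`, `n_a`, `n_b`, `mean_a`, `mean_b`.
#' @export
compare_ligands <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("insufficient replicates: need n >= 2 per group (got ",
         length(a), " and ", length(b), ")")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(statistic = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                p_value = if (eq) 1 else 0, df = NA_real_)
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    res <- list(statistic = unname(tt$statistic),
                p_value = tt$p.value, df = unname(tt$parameter))
  }
  structure(list(statistic = res$statistic, p_value = res$p_value,
                 test_name = "Welch two-sample t-test (two-sided)",
                 df = res$df, n_a = length(a), n_b = length(b),
                 mean_a = mean(a), mean_b = mean(b)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: t = %.3g, p = %.3g (n=%d vs n=%d)\n", x$test_name,
              x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}
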