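# Aliphatic linker-length proposal for bitopic ligand design: pure reach
# arithmetic mapping an anchor-to-pocket distance onto candidate methylene
# counts.

#' Default linker reach calibration
#'
#' Loaded from the packaged default configuration
#' (`inst/extdata/default_config.yaml`), not hard-coded: `per_methylene_A`
#' is the projected length a methylene unit adds to an extended (all-anti)
#' chain, and `anchor_offset_A` covers the fixed reach beyond the chain
#' (terminal warhead group plus the polar-contact gap to the target).
#'
#' @return named list with `per_methylene_A`, `anchor_offset_A`,
#'   `tolerance_A`.
#' @export
linker_defaults <- function() {
  cfg <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                     package = "mdpolar"))
  cfg$linker
}

#' Propose aliphatic linker lengths for a target reach
#'
#' Models the reach of a C_n linker as
#' `modeled_reach(n) = anchor_offset_A + n * per_methylene_A` and returns
#' every n whose reach is within `tolerance_A` of the target distance,
#' plus the nearest candidates just outside tolerance (flagged), sorted by
#' absolute slack. Deterministic given the calibration.
#'
#' @param target_distance_A measured anchor-to-pocket distance, Angstrom.
#' @param per_methylene_A,anchor_offset_A,tolerance_A calibration; defaults
#'   from [linker_defaults()].
#' @param n_range integer range of chain lengths to consider.
#' @return list of class `"linker_proposal"`: `target_distance_A`,
#'   calibration fields, and `candidates` data.frame (`n_carbons`,
#'   `modeled_reach_A`, `slack_A`, `within_tolerance`).
#' @export
propose_linker_lengths <- function(target_distance_A,
                                   per_methylene_A = NULL,
                                   anchor_offset_A = NULL,
                                   tolerance_A = NULL,
                                   n_range = 1:12) {
  defaults <- linker_defaults()
  if (is.null(per_methylene_A)) per_methylene_A <- defaults$per_methylene_A
  if (is.null(anchor_offset_A)) anchor_offset_A <- defaults$anchor_offset_A
  if (is.null(tolerance_A)) tolerance_A <- defaults$tolerance_A
  if (target_distance_A <= 0)
    stop("target distance must be positive")
  if (target_distance_A <= anchor_offset_A)
    stop("target distance (", target_distance_A,
         " A) must exceed the anchor offset (", anchor_offset_A, " A)")
  reach <- anchor_offset_A + n_range * per_methylene_A
  slack <- reach - target_distance_A
  within <- abs(slack) <= tolerance_A
  cand <- data.frame(n_carbons = n_range, modeled_reach_A = reach,
                     slack_A = slack, within_tolerance = within)
  # keep all in-tolerance n plus the nearest flagged neighbours outside
  keep <- within
  out_idx <- which(!within)
  if (length(out_idx) > 0) {
    nearest <- out_idx[order(abs(slack[out_idx]))[seq_len(min(2, length(out_idx)))]]
    keep[nearest] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(abs(cand$slack_A), cand$n_carbons), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(target_distance_A = target_distance_A,
                 per_methylene_A = per_methylene_A,
                 anchor_offset_A = anchor_offset_A,
                 tolerance_A = tolerance_A,
                 candidates = cand),
            class = "linker_proposal")
}

#' @export
print.linker_proposal <- function(x, ...) {
  cat(sprintf(
    "linker proposal for target %.2f A (offset %.2f + n x %.2f A, tol %.2f A)\n",
    x$target_distance_A, x$anchor_offset_A, x$per_methylene_A,
    x$tolerance_A))
  print(x$candidates, row.names = FALSE)
  invisible(x)
}
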