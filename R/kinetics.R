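#' Detect the membrane-insertion event in a trajectory
#'
#' The first passage time W is the earliest frame time t at which the solute
#' center of mass sits at or below the membrane surface `surface_z` and stays
#' there for all frames in \[t, t + persistence\]. The persistence window
#' rejects grazing contacts where the molecule touches the surface for a
#' frame or two and returns to the water phase. If no such t exists the
#' replicate is censored at the last frame time.
#'
#' @param traj A `mem_trajectory`.
#' @param surface_z Surface definition in A; defaults to the proximal (upper)
#'   phosphate plane of the trajectory's bilayer model.
#' @param persistence Required residence time below the surface in ns
#'   (default 0.5).
#' @param replicate_id Optional label carried into the result.
#' @return A one-row tibble: `replicate_id`, `inserted`, `W` (ns), `censored`.
#' @examples
#' bil <- build_bilayer_model("POPC")
#' kp <- kinetic_params(v = 2, D = 1, max_time = 20, seed = 1)
#' tr <- simulate_insertion_trajectory(bil, kp)
#' detect_insertion(tr)
#' @export
detect_insertion <- function(traj, surface_z = NULL, persistence = 0.5,
                             replicate_id = NA_character_) {
  stopifnot(inherits(traj, "mem_trajectory"))
  if (nrow(traj$frames) == 0) abort("empty trajectory: no frames to analyse")
  surface_z <- surface_z %||% traj$meta$surface_z %||%
    traj$bilayer$phosphate_plane_upper
  if (is.null(surface_z)) abort("`surface_z` is needed (no bilayer model attached)")
  stopifnot("`persistence` must be >= 0" = persistence >= 0)

  z <- traj$drug_com$z
  t <- traj$drug_com$time_ns
  if (z[1] <= surface_z) {
    abort("solute starts at or below `surface_z`: invalid insertion setup")
  }
  below <- z <= surface_z
  dt <- if (length(t) > 1) t[2] - t[1] else 0
  w_frames <- if (dt > 0) ceiling(persistence / dt - 1e-9) else 0

  # first index i such that below[i .. i + w_frames] are all TRUE
  run_ok <- sustained_below(below, w_frames)
  idx <- which(run_ok)[1]
  if (is.na(idx)) {
    tibble(replicate_id = replicate_id, inserted = FALSE,
           W = t[length(t)], censored = TRUE)
  } else {
    tibble(replicate_id = replicate_id, inserted = TRUE,
           W = t[idx], censored = FALSE)
  }
}

# TRUE at i when below[i..i+w] (clipped to the series end would fail) are all TRUE
sustained_below <- function(below, w) {
  n <- length(below)
  if (w == 0) return(below)
  if (n <= w) return(rep(FALSE, n))
  cs <- cumsum(c(0, below))
  ok <- (cs[(w + 2):(n + 1)] - cs[1:(n - w)]) == (w + 1)
  c(ok, rep(FALSE, w))
}

#' Mean first passage time over replicates
#'
#' Arithmetic mean and standard error of the uncensored first-passage times.
#' Censored replicates are dropped (policy `"drop"`, with a warning when more
#' than 25% are censored) or raise an error (policy `"error"`).
#'
#' @param results Tibble of [detect_insertion()] rows (columns `W`,
#'   `censored`).
#' @param censor_policy `"drop"` or `"error"`.
#' @return A one-row tibble: `W_mean`, `W_sem` (ns), `n_inserted`,
#'   `n_censored`.
#' @export
mean_first_passage <- function(results, censor_policy = c("drop", "error")) {
  censor_policy <- match.arg(censor_policy)
  stopifnot(all(c("W", "censored") %in% names(results)))
  n_cens <- sum(results$censored)
  if (censor_policy == "error" && n_cens > 0) {
    abort(paste0(n_cens, " censored replicate(s) under policy 'error'"))
  }
  w <- results$W[!results$censored]
  if (length(w) == 0) abort("all replicates censored: no first-passage times to average")
  if (n_cens / nrow(results) > 0.25) {
    warn(sprintf("%d of %d replicates censored (> 25%%); <W> may be biased low",
                 n_cens, nrow(results)))
  }
  tibble(
    W_mean = mean(w),
    W_sem = if (length(w) > 1) sd(w) / sqrt(length(w)) else NA_real_,
    n_inserted = length(w),
    n_censored = n_cens
  )
}

#' Insertion association constant K_in
#'
#' K_in = A * L_z / <W>, with the lateral membrane area A (A^2) times the
#' water-layer thickness L_z (A) converted from A^3 to M^-1 via Avogadro's
#' number (1 A^3 = 6.02214e-4 M^-1) and <W> converted from ns to s, giving
#' K_in in M^-1 s^-1.
#'
#' @param A Lateral membrane area in A^2.
#' @param L_z Water-layer thickness in A.
#' @param W_mean Mean first passage time in ns.
#' @return K_in in M^-1 s^-1 (vectorised over its arguments).
#' @examples
#' compute_kin(A = 4160, L_z = 30, W_mean = 20)  # ~3.76e9 M^-1 s^-1
#' @export
compute_kin <- function(A, L_z, W_mean) {
  if (any(A <= 0) || any(L_z <= 0) || any(W_mean <= 0)) {
    abort("`A`, `L_z` and `W_mean` must all be positive")
  }
  A * L_z * C_VOL / (W_mean * 1e-9)
}

#' Aggregate replicates into a K_in estimate
#'
#' Runs [mean_first_passage()] and [compute_kin()] for one analogue x lipid
#' cell and returns a `kin_estimate` carrying all inputs, so the internal
#' consistency K_in = A*L_z*C_vol/(W_mean*1e-9) can always be re-checked.
#'
#' @param results Tibble of first-passage results (see
#'   [mean_first_passage()]).
#' @param A Lateral area in A^2.
#' @param L_z Water-layer thickness in A.
#' @param analogue,lipid Labels.
#' @param censor_policy Passed to [mean_first_passage()].
#' @return A `kin_estimate` object.
#' @export
kin_estimate <- function(results, A, L_z, analogue = NA_character_,
                         lipid = NA_character_, censor_policy = "drop") {
  mfp <- mean_first_passage(results, censor_policy)
  structure(
    list(
      analogue = analogue, lipid = lipid, A = A, L_z = L_z,
      W_mean = mfp$W_mean, W_sem = mfp$W_sem,
      n_inserted = mfp$n_inserted, n_censored = mfp$n_censored,
      K_in = compute_kin(A, L_z, mfp$W_mean)
    ),
    class = "kin_estimate"
  )
}

#' @export
print.kin_estimate <- function(x, ...) {
  cat(sprintf("<kin_estimate> %s in %s: K_in = %.3g M^-1 s^-1 (<W> = %.2f ns, n = %d + %d censored)\n",
              x$analogue, x$lipid, x$K_in, x$W_mean, x$n_inserted, x$n_censored))
  invisible(x)
}

#' @describeIn kin_estimate One row per estimate with all fields.
#' @param x A `kin_estimate`.
#' @param ... Unused.
#' @export
tidy.kin_estimate <- function(x, ...) {
  tibble(
    analogue = x$analogue, lipid = x$lipid, A = x$A, L_z = x$L_z,
    W_mean = x$W_mean, W_sem = x$W_sem,
    n_inserted = x$n_inserted, n_censored = x$n_censored, K_in = x$K_in
  )
}

#' @describeIn kin_estimate One-row model summary (K_in and sampling counts).
#' @export
glance.kin_estimate <- function(x, ...) {
  tibble(K_in = x$K_in, W_mean = x$W_mean, W_sem = x$W_sem,
         n_inserted = x$n_inserted, n_censored = x$n_censored)
}

#' Percentage by which one association constant lags a reference
#'
#' `(1 - K_other/K_ref) * 100`: positive when `K_other` is slower (smaller)
#' than the reference.
#'
#' @param K_ref Reference association constant (> 0).
#' @param K_other Compared association constant.
#' @return Percentage difference (vectorised).
#' @examples
#' percent_slower(3.71e9, 2.75e9)  # EPI ~26% slower than DOX
#' @export
percent_slower <- function(K_ref, K_other) {
  if (any(K_ref <= 0)) abort("`K_ref` must be positive")
  (1 - K_other / K_ref) * 100
}

#' Rank analogues by association constant
#'
#' Stable descending sort by K_in; ties are broken by label so the order is
#' deterministic.
#'
#' @param kin_table Tibble with columns `analogue` and `K_in` (one row per
#'   analogue).
#' @return Character vector of analogue labels, fastest inserter first.
#' @export
rank_analogues <- function(kin_table) {
  stopifnot(all(c("analogue", "K_in") %in% names(kin_table)),
            nrow(kin_table) > 0)
  if (anyDuplicated(kin_table$analogue)) {
    abort("duplicate analogue labels in `kin_table`")
  }
  kin_table$analogue[order(-kin_table$K_in, kin_table$analogue)]
}

#' Per-analogue ratio of association constants between two lipids
#'
#' Element-wise K_in ratio (table B over table A) per analogue, plus the
#' arithmetic mean ratio as the `mean_ratio` attribute.
#'
#' @param kin_a,kin_b Tibbles with columns `analogue`, `K_in` over the same
#'   analogue set.
#' @return Tibble `analogue`, `K_in_a`, `K_in_b`, `ratio`, with attribute
#'   `mean_ratio`.
#' @export
lipid_ratio <- function(kin_a, kin_b) {
  stopifnot(all(c("analogue", "K_in") %in% names(kin_a)),
            all(c("analogue", "K_in") %in% names(kin_b)))
  only_a <- setdiff(kin_a$analogue, kin_b$analogue)
  only_b <- setdiff(kin_b$analogue, kin_a$analogue)
  if (length(only_a) || length(only_b)) {
    abort(paste0(
      "analogue sets differ",
      if (length(only_a)) paste0("; only in first: ", paste(only_a, collapse = ", ")),
      if (length(only_b)) paste0("; only in second: ", paste(only_b, collapse = ", "))
    ))
  }
  out <- dplyr::inner_join(
    dplyr::select(kin_a, "analogue", K_in_a = "K_in"),
    dplyr::select(kin_b, "analogue", K_in_b = "K_in"),
    by = "analogue"
  )
  out <- dplyr::mutate(out, ratio = .data$K_in_b / .data$K_in_a)
  attr(out, "mean_ratio") <- mean(out$ratio)
  out
}
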