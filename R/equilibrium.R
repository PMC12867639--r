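# One-shot Nash equilibria and the repeated game's subgame-perfect
# equilibrium payoff region.
#
# With patient players, the Folk theorem characterizes the payoffs
# sustainable in a subgame perfect equilibrium of the infinitely repeated
# game: every payoff vector that is feasible (a convex combination of stage
# payoffs, realized as a long-run average) and individually rational (each
# player gets at least their pure-action minimax). Individual rationality is
# applied with a weak inequality so that boundary points reachable by
# repeating stage Nash equilibria (e.g. full defection in the linear game)
# are included.

# All contribution profiles as an m x n integer matrix, expand.grid order
# (player 1 varies fastest). Guarded against combinatorial blowup.
all_profiles <- function(spec, max_profiles = 1e7) {
  m <- prod(spec$e + 1)
  if (m > max_profiles)
    stop("profile space too large: ", format(m), " > ", format(max_profiles))
  as.matrix(do.call(expand.grid, lapply(spec$e, function(ei) 0:ei)))
}

# Payoffs for every row of a profile matrix, m x n.
profile_payoffs <- function(spec, profiles) {
  kept <- sweep(-profiles, 2, spec$e, "+")
  Ck <- drop(profiles %*% spec$p_num) # C * p_den, exact integers
  if (spec$reward$kind == "linear") {
    kept + Ck / (spec$p_den * spec$n)
  } else {
    rw <- spec$reward
    met <- Ck * rw$theta_den >= rw$theta_num * spec$p_den
    kept + rw$r * met
  }
}

#' Enumerate all pure-strategy one-shot Nash equilibria
#'
#' Exhaustive best-response check over all integer contribution profiles: a
#' profile is a Nash equilibrium iff no player can raise their own payoff by
#' a unilateral deviation.
#'
#' @param spec A `pgg_game`.
#' @param max_profiles Guard on the profile-space size.
#' @return Integer matrix, one Nash profile per row (zero rows if none).
#' @examples
#' enumerate_pure_nash(pgg_game(c(2, 2), c(1.6, 1.6)))  # only (0, 0)
#' @export
enumerate_pure_nash <- function(spec, max_profiles = 1e7) {
  profiles <- all_profiles(spec, max_profiles)
  pay <- profile_payoffs(spec, profiles)
  dims <- spec$e + 1L
  n <- spec$n
  best <- matrix(TRUE, nrow(profiles), n)
  for (i in seq_len(n)) {
    arr <- array(pay[, i], dim = dims)
    others <- setdiff(seq_len(n), i)
    bmax <- apply(arr, others, max)
    best[, i] <- as.vector(sweep(arr, others, bmax, "-") >= -1e-9)
  }
  eq <- profiles[rowSums(best) == n, , drop = FALSE]
  rownames(eq) <- NULL
  eq
}

#' Pure-action minimax payoffs
#'
#' For each player, the payoff they can guarantee regardless of the others'
#' contributions: `min` over opponents' profiles of `max` over the player's
#' own contribution. This is the individual-rationality floor of the Folk
#' theorem. In linear games with all `p_i < n` the minimax equals the
#' endowment (keep everything).
#'
#' @inheritParams enumerate_pure_nash
#' @return Numeric vector of minimax payoffs.
#' @export
minimax_payoffs <- function(spec, max_profiles = 1e7) {
  profiles <- all_profiles(spec, max_profiles)
  pay <- profile_payoffs(spec, profiles)
  dims <- spec$e + 1L
  vapply(seq_len(spec$n), function(i) {
    arr <- array(pay[, i], dim = dims)
    others <- setdiff(seq_len(spec$n), i)
    min(apply(arr, others, max))
  }, numeric(1))
}

# Counterclockwise convex hull of 2-column point matrix; returns vertex rows.
hull_ccw <- function(pts) {
  idx <- grDevices::chull(pts)
  v <- pts[idx, , drop = FALSE]
  if (nrow(v) >= 3) {
    area2 <- sum(v[, 1] * v[c(2:nrow(v), 1), 2] - v[c(2:nrow(v), 1), 1] * v[, 2])
    if (area2 < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  }
  v
}

# Sutherland-Hodgman clip of a CCW polygon by half-plane a.x >= b.
clip_halfplane <- function(poly, a, b, eps = 1e-9) {
  if (nrow(poly) == 0) return(poly)
  keep <- drop(poly %*% a) >= b - eps
  out <- list()
  m <- nrow(poly)
  for (k in seq_len(m)) {
    j <- if (k == m) 1L else k + 1L
    pk <- poly[k, ]; pj <- poly[j, ]
    if (keep[k]) out[[length(out) + 1]] <- pk
    if (xor(keep[k], keep[j])) {
      t <- (b - sum(a * pk)) / sum(a * (pj - pk))
      out[[length(out) + 1]] <- pk + t * (pj - pk)
    }
  }
  if (length(out) == 0) return(poly[0, , drop = FALSE])
  res <- do.call(rbind, out)
  res[!duplicated(round(res, 9)), , drop = FALSE]
}

#' Subgame-perfect equilibrium payoff region of the repeated game
#'
#' Feasible set: convex hull of all stage-game payoff vectors. Equilibrium
#' region: its intersection with the individually rational half-spaces
#' `pi_i >= minimax_i` (weak inequality). For two players the region is an
#' explicit polygon with counterclockwise vertices; for larger groups the
#' region is represented by the stage-payoff set and queried by membership.
#'
#' @inheritParams enumerate_pure_nash
#' @return A `pgg_region` with fields `feasible_vertices` (n = 2 only),
#'   `region_vertices` (n = 2 only), `minimax`, `payoff_points`, `game`.
#' @export
spe_region <- function(spec, max_profiles = 1e7) {
  profiles <- all_profiles(spec, max_profiles)
  pay <- profile_payoffs(spec, profiles)
  mm <- minimax_payoffs(spec, max_profiles)
  feas <- NULL
  region <- NULL
  if (spec$n == 2) {
    upts <- unique(round(pay, 9))
    dimnames(upts) <- list(NULL, paste0("pi", 1:2))
    feas <- if (nrow(upts) >= 3) hull_ccw(upts) else upts
    region <- feas
    if (nrow(region) >= 3)
      for (i in 1:2) {
        a <- c(0, 0); a[i] <- 1
        region <- clip_halfplane(region, a, mm[i])
      }
  }
  structure(list(feasible_vertices = feas, region_vertices = region,
                 minimax = mm, payoff_points = pay, game = spec),
            class = "pgg_region")
}

#' @export
print.pgg_region <- function(x, ...) {
  cat("SPE payoff region (Folk theorem)\n")
  cat("  minimax:", paste(format(x$minimax), collapse = ", "), "\n")
  if (!is.null(x$region_vertices)) {
    cat("  region vertices (CCW):\n")
    print(round(x$region_vertices, 4))
  } else {
    cat("  n =", x$game$n, "-- membership by query, see contains_payoff()\n")
  }
  invisible(x)
}

# Membership of v in conv(rows of P), via Frank-Wolfe projection.
# Returns TRUE iff the squared distance from v to the hull is < tol.
in_hull <- function(P, v, tol = 1e-6, maxit = 5000) {
  d0 <- rowSums(sweep(P, 2, v)^2)
  x <- P[which.min(d0), ]
  for (it in seq_len(maxit)) {
    g <- x - v
    s <- P[which.min(drop(P %*% g)), ]
    gap <- sum(g * (x - s))
    if (sum(g^2) < tol^2 || gap < tol^2 / 4) break
    dxs <- s - x
    step <- min(1, max(0, -sum(g * dxs) / sum(dxs^2)))
    if (!is.finite(step) || step == 0) break
    x <- x + step * dxs
  }
  sum((x - v)^2) < tol
}

# Point in CCW convex polygon, weak (boundary included).
point_in_poly <- function(poly, v, eps = 1e-7) {
  m <- nrow(poly)
  if (m == 0) return(FALSE)
  if (m == 1) return(all(abs(poly[1, ] - v) < eps))
  if (m == 2) {
    d <- poly[2, ] - poly[1, ]
    w <- v - poly[1, ]
    cr <- d[1] * w[2] - d[2] * w[1]
    t <- sum(w * d) / sum(d^2)
    return(abs(cr) < eps * sqrt(sum(d^2)) && t >= -eps && t <= 1 + eps)
  }
  for (k in seq_len(m)) {
    j <- if (k == m) 1L else k + 1L
    d <- poly[j, ] - poly[k, ]
    w <- v - poly[k, ]
    if (d[1] * w[2] - d[2] * w[1] < -eps) return(FALSE)
  }
  TRUE
}

#' Test whether a payoff vector lies in the SPE region
#'
#' True iff the vector is feasible (in the convex hull of stage payoffs) and
#' weakly individually rational (`v_i >= minimax_i` for all players).
#'
#' @param region A `pgg_region` from [spe_region()].
#' @param v Numeric payoff vector.
#' @return `TRUE` or `FALSE`.
#' @export
contains_payoff <- function(region, v) {
  if (length(v) != region$game$n)
    stop("payoff vector dimension ", length(v), " does not match n = ",
         region$game$n)
  if (any(v < region$minimax - 1e-9)) return(FALSE)
  if (!is.null(region$feasible_vertices))
    return(point_in_poly(region$feasible_vertices, v))
  in_hull(region$payoff_points, v)
}

#' Is full cooperation sustainable as a subgame perfect equilibrium?
#'
#' Full cooperation (every player contributing their entire endowment each
#' round) is feasible by construction; it is an SPE payoff iff it is
#' individually rational, i.e. the full-cooperation payoff of every player
#' weakly exceeds their minimax. In the linear game this fails exactly when
#' a high-endowment, low-productivity player would earn less than their
#' endowment under full cooperation.
#'
#' @inheritParams enumerate_pure_nash
#' @return `TRUE` or `FALSE`.
#' @export
full_cooperation_is_spe <- function(spec, max_profiles = 1e7) {
  v <- payoffs(spec, spec$e)
  all(v >= minimax_payoffs(spec, max_profiles) - 1e-9)
}
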