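# Birth-death lineage simulation and time-variable Poisson preservation.
# Times run in Ma, decreasing towards the present (0 Ma).

#' Piecewise-constant birth-death rate schedule
#'
#' @param lambda,mu Speciation and extinction rates per lineage per Myr, one
#'   value per interval (length = `length(shifts) + 1`).
#' @param shifts Shift times in Ma, strictly descending; empty for constant
#'   rates.
#' @return A list of class `bd_schedule`.
#' @export
bd_schedule <- function(lambda, mu, shifts = numeric(0)) {
  stopifnot(length(lambda) == length(shifts) + 1,
            length(mu) == length(shifts) + 1,
            all(lambda >= 0), all(mu >= 0),
            !is.unsorted(rev(shifts), strictly = TRUE) || length(shifts) < 2)
  structure(list(lambda = lambda, mu = mu, shifts = shifts),
            class = "bd_schedule")
}

# Rates in force at age t (Ma): interval k holds for shifts[k-1] >= t > shifts[k].
schedule_index <- function(t, shifts) {
  findInterval(-t, -c(Inf, shifts), rightmost.closed = FALSE)
}

#' Simulate a birth-death clade with rejection on final species count
#'
#' Forward continuous-time birth-death simulation starting from a single
#' lineage at `root_age`, with piecewise-constant speciation and extinction
#' rates. Simulations are resampled until the total number of species ever
#' alive falls inside `accept_range` (the count before any preservation
#' sampling, which can only reduce observed richness).
#'
#' @param root_age Clade origin, Ma. Default 25.
#' @param schedule A [bd_schedule()].
#' @param accept_range Length-2 integer vector, inclusive bounds on total
#'   species count. Default `c(100, 500)`.
#' @param seed Integer seed; output deterministic given the seed.
#' @param max_attempts Attempts before giving up.
#' @return Tibble with columns `lineage`, `origin`, `extinction` (0 for
#'   lineages extant at present). The number of rejected attempts is in the
#'   `"attempts"` attribute.
#' @export
simulate_bd <- function(root_age = 25, schedule, accept_range = c(100, 500),
                        seed = NULL, max_attempts = 1000) {
  stopifnot(inherits(schedule, "bd_schedule"),
            length(accept_range) == 2, accept_range[1] >= 1,
            accept_range[2] >= accept_range[1])
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    res <- bd_forward(root_age, schedule, hard_cap = accept_range[2])
    if (!is.null(res) && nrow(res) >= accept_range[1]) {
      res$lineage <- sprintf("t%03d", seq_len(nrow(res)))
      res <- res[, c("lineage", "origin", "extinction")]
      attr(res, "attempts") <- attempt
      return(res)
    }
  }
  stop("no accepted birth-death simulation in ", max_attempts,
       " attempts; widen accept_range or adjust the rate schedule",
       call. = FALSE)
}

# One forward pass; returns NULL if the species count exceeds hard_cap.
bd_forward <- function(root_age, schedule, hard_cap) {
  origin <- root_age
  extinction <- NA_real_
  queue <- 1L            # indices of lineages still to be simulated
  births <- numeric(0)   # pending birth times
  n <- 1L
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    t <- origin[i]
    repeat {
      k <- schedule_index(t, schedule$shifts)
      seg_end <- if (k <= length(schedule$shifts)) schedule$shifts[k] else 0
      tot <- schedule$lambda[k] + schedule$mu[k]
      if (tot == 0) {
        t <- seg_end
      } else {
        wait <- stats::rexp(1, tot)
        if (t - wait <= seg_end) {
          t <- seg_end
        } else {
          t <- t - wait
          if (runif(1) < schedule$lambda[k] / tot) {
            n <- n + 1L
            if (n > hard_cap) return(NULL)
            origin[n] <- t
            extinction[n] <- NA_real_
            queue <- c(queue, n)
          } else {
            extinction[i] <- t
            break
          }
        }
      }
      if (t <= 0) break
    }
    if (is.na(extinction[i])) extinction[i] <- 0
  }
  tibble::tibble(origin = origin, extinction = extinction)
}

#' Draw a time-variable preservation regime
#'
#' Six piecewise-constant preservation rates (expected occurrences per
#' lineage per Myr) are drawn log-uniformly between 0.25 and 2.5, i.e.
#' `q ~ exp(U(log 0.25, log 2.5))`, so most rates are small. Rate shifts are
#' fixed at 23, 15, 8, 5.3 and 2.6 Ma. Optional gap intervals force the rate
#' to exactly zero (complete preservation failure) within them.
#'
#' @param seed Integer seed.
#' @param heterogeneity `"none"` or `"gamma"`; with `"gamma"`, per-lineage
#'   rate multipliers are later drawn from Gamma(`alpha`, `alpha`) (mean 1).
#' @param alpha Gamma shape (= rate) for across-lineage heterogeneity;
#'   default 0.5.
#' @param gaps List of length-2 vectors `c(from, to)` in Ma (from > to) in
#'   which preservation is set to zero.
#' @param root_age Oldest age covered by the regime, Ma.
#' @param shifts Rate shift times, Ma, descending.
#' @param bounds Rate bounds for the log-uniform draw.
#' @return List of class `preservation_regime`: `segments` (tibble `base`,
#'   `top`, `q`), `alpha` (`Inf` when homogeneous), `heterogeneity`.
#' @export
draw_preservation_regime <- function(seed = NULL,
                                     heterogeneity = c("none", "gamma"),
                                     alpha = 0.5, gaps = list(),
                                     root_age = 25,
                                     shifts = c(23, 15, 8, 5.3, 2.6),
                                     bounds = c(0.25, 2.5)) {
  heterogeneity <- match.arg(heterogeneity)
  if (!is.null(seed)) set.seed(seed)
  rates <- exp(runif(length(shifts) + 1, log(bounds[1]), log(bounds[2])))
  base <- c(root_age, shifts)
  top <- c(shifts, 0)
  seg <- tibble::tibble(base = base, top = top, q = rates)
  for (gp in gaps) {
    seg <- apply_gap(seg, max(gp), min(gp))
  }
  structure(list(segments = seg,
                 alpha = if (heterogeneity == "gamma") alpha else Inf,
                 heterogeneity = heterogeneity),
            class = "preservation_regime")
}

# Split regime segments so that [from, to] (Ma) has rate exactly 0.
apply_gap <- function(seg, from, to) {
  out <- list()
  for (i in seq_len(nrow(seg))) {
    b <- seg$base[i]; tp <- seg$top[i]; q <- seg$q[i]
    lo <- max(tp, to); hi <- min(b, from)
    if (hi <= lo) {            # no overlap with the gap
      out[[length(out) + 1]] <- tibble::tibble(base = b, top = tp, q = q)
    } else {
      if (b > hi) out[[length(out) + 1]] <- tibble::tibble(base = b, top = hi, q = q)
      out[[length(out) + 1]] <- tibble::tibble(base = hi, top = lo, q = 0)
      if (lo > tp) out[[length(out) + 1]] <- tibble::tibble(base = lo, top = tp, q = q)
    }
  }
  dplyr::bind_rows(out)
}

#' Sample fossil occurrences from lineages under a preservation regime
#'
#' Per lineage, a gamma rate multiplier `g ~ Gamma(alpha, alpha)` is drawn
#' (1 under the homogeneous model) and occurrence times are generated as an
#' inhomogeneous Poisson process with intensity `q(t) * g` over the lineage's
#' lifespan. Within each constant-rate segment the process is homogeneous, so
#' sampling is exact (Poisson count + uniform times per segment overlap).
#' Lineages with zero occurrences are unsampled: they are absent from the
#' observable record.
#'
#' @param lineages Tibble from [simulate_bd()].
#' @param regime A [draw_preservation_regime()] object.
#' @param seed Integer seed.
#' @return List of class `simulated_record`: `occurrences` (tibble `taxon`,
#'   `age`), `lineages`, `multipliers` (tibble `lineage`, `g`), `regime`,
#'   `seed`.
#' @export
simulate_fossils <- function(lineages, regime, seed = NULL) {
  stopifnot(inherits(regime, "preservation_regime"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(lineages)
  g <- if (is.finite(regime$alpha)) {
    rgamma(n, shape = regime$alpha, rate = regime$alpha)
  } else {
    rep(1, n)
  }
  seg <- regime$segments
  occ <- vector("list", n)
  for (i in seq_len(n)) {
    lo <- max(lineages$extinction[i], 0)
    hi <- lineages$origin[i]
    ages <- numeric(0)
    for (s in seq_len(nrow(seg))) {
      a <- max(lo, seg$top[s]); b <- min(hi, seg$base[s])
      if (b <= a || seg$q[s] == 0) next
      k <- rpois(1, seg$q[s] * g[i] * (b - a))
      if (k > 0) ages <- c(ages, runif(k, a, b))
    }
    if (length(ages) > 0) {
      occ[[i]] <- tibble::tibble(taxon = lineages$lineage[i], age = ages)
    }
  }
  structure(list(occurrences = dplyr::bind_rows(occ),
                 lineages = lineages,
                 multipliers = tibble::tibble(lineage = lineages$lineage,
                                              g = g),
                 regime = regime, seed = seed),
            class = "simulated_record")
}

#' True standing diversity per time bin
#'
#' Counts lineages whose lifespan intersects each bin. Bins are half-open
#' `(top, base]`: a lineage going extinct exactly on a bin boundary is
#' counted in the older bin only.
#'
#' @param lineages Tibble with `origin` and `extinction` columns (Ma).
#' @param bins A [time_bins()] tibble.
#' @return Tibble with columns `bin`, `base`, `top`, `d_true`.
#' @export
true_diversity <- function(lineages, bins) {
  d <- vapply(seq_len(nrow(bins)), function(b) {
    sum(lineages$origin > bins$top[b] & lineages$extinction < bins$base[b])
  }, numeric(1))
  tibble::tibble(bin = bins$bin, base = bins$base, top = bins$top, d_true = d)
}

#' Scenario presets for the simulation study
#'
#' Named birth-death + preservation configurations used in the validation
#' study. The preservation regime of every scenario draws six rates per Eq.
#' `q ~ exp(U(log 0.25, log 2.5))` with shifts at 23, 15, 8, 5.3, 2.6 Ma:
#' \describe{
#'   \item{A}{constant rates (lambda 0.3, mu 0.1 per lineage per Myr)}
#'   \item{B}{as A, plus complete preservation gaps 15-8 and 5.3-2.6 Ma}
#'   \item{C}{diversification shift at 12 Ma (lambda 0.4 to 0.1, mu 0.05 to
#'     0.25): diversity rises then declines}
#'   \item{D}{as A, plus gamma(0.5, 0.5) across-lineage rate heterogeneity}
#'   \item{E}{mass-extinction pulse (mu 2.5 between 10 and 9.5 Ma)}
#'   \item{F}{as C, plus gamma(0.5, 0.5) heterogeneity}
#' }
#'
#' @param scenario One of `"A"`..`"F"`.
#' @return List with elements `schedule` ([bd_schedule()]), `gaps`,
#'   `heterogeneity`, `alpha`, `root_age`.
#' @export
scenario_preset <- function(scenario = c("A", "B", "C", "D", "E", "F")) {
  scenario <- match.arg(scenario)
  preset <- list(schedule = bd_schedule(0.3, 0.1), gaps = list(),
                 heterogeneity = "none", alpha = 0.5, root_age = 25)
  shifted <- bd_schedule(lambda = c(0.4, 0.1), mu = c(0.05, 0.25),
                         shifts = 12)
  if (scenario == "B") preset$gaps <- list(c(15, 8), c(5.3, 2.6))
  if (scenario %in% c("C", "F")) preset$schedule <- shifted
  if (scenario %in% c("D", "F")) preset$heterogeneity <- "gamma"
  if (scenario == "E") {
    preset$schedule <- bd_schedule(lambda = c(0.3, 0.3, 0.3),
                                   mu = c(0.1, 2.5, 0.1),
                                   shifts = c(10, 9.5))
  }
  preset
}
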