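# Minimal off-lattice 2D cell population: cell types with base phenotype
# rates, stochastic division and death, persistent random-walk motility,
# volume-exclusion relaxation, and confluence measurement. The population
# is stored column-wise (vectors/matrices over cells) so every step is
# vectorized; randomness comes from the session RNG in a fixed draw
# order, which makes runs bit-reproducible under a fixed seed.

#' Define a cell type
#'
#' @param name Type name.
#' @param radius Cell radius (um, > 0); the cell volume used for exchange
#'   is the volume of a sphere of this radius.
#' @param prolif_rate,apop_rate,necrosis_rate Base phenotype rates
#'   (1/min, >= 0).
#' @param motility_speed Base migration speed (um/min, >= 0).
#' @param persistence_time Mean time between direction changes of the
#'   persistent random walk (min, > 0).
#' @param uptake Named numeric vector of per-substrate uptake rates
#'   (1/min).
#' @param pd Named list of [pd_params()] per PD substrate.
#' @param moa Named list of [moa_config()] per PD substrate.
#' @return An object of class `cell_type_def`.
#' @export
cell_type <- function(name, radius = 10, prolif_rate = 0, apop_rate = 0,
                      necrosis_rate = 0, motility_speed = 0,
                      persistence_time = 5, uptake = numeric(0),
                      pd = list(), moa = list()) {
  if (radius <= 0) stop("radius must be > 0")
  rates <- c(prolif_rate, apop_rate, necrosis_rate, motility_speed)
  if (any(rates < 0)) stop("base rates must be >= 0")
  if (persistence_time <= 0) stop("persistence_time must be > 0")
  structure(list(name = name, radius = radius,
                 prolif_rate = prolif_rate, apop_rate = apop_rate,
                 necrosis_rate = necrosis_rate,
                 motility_speed = motility_speed,
                 persistence_time = persistence_time,
                 uptake = uptake, pd = pd, moa = moa,
                 volume = 4 / 3 * pi * radius^3),
            class = "cell_type_def")
}

#' Create a cell population
#'
#' @param x,y Initial positions (um).
#' @param type Character vector of type names (recycled).
#' @param types Named list of [cell_type()] definitions.
#' @param pd_substrates Character vector of PD substrate names; the
#'   population carries an internalized-substrate matrix `A` and a damage
#'   matrix `D` with one column per PD substrate.
#' @return An object of class `cell_population`.
#' @export
cell_population <- function(x = numeric(0), y = numeric(0),
                            type = character(0), types,
                            pd_substrates = character(0)) {
  n <- length(x)
  stopifnot(length(y) == n)
  type <- rep_len(type, n)
  if (n && !all(type %in% names(types)))
    stop("unknown cell type in layout")
  ti <- match(type, names(types))
  mk <- function() matrix(0, n, length(pd_substrates),
                          dimnames = list(NULL, pd_substrates))
  pop <- list(id = seq_len(n), x = x, y = y, type = ti,
              types = types, pd_substrates = pd_substrates,
              A = mk(), D = mk(),
              theta = rep(0, n),
              rate_prolif = numeric(n), rate_apop = numeric(n),
              rate_necrosis = numeric(n), speed = numeric(n),
              next_id = n + 1L)
  pop <- reset_rates(pop)
  if (n) pop$theta <- stats::runif(n, 0, 2 * pi)
  structure(pop, class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("cell_population: %d cells, %d type(s), %d PD substrate(s)\n",
              length(x$x), length(x$types), length(x$pd_substrates)))
  invisible(x)
}

# number of live cells
ncells <- function(cells) length(cells$x)

# Set current rates to the base rates of each cell's type.
reset_rates <- function(cells) {
  tdef <- cells$types
  pick <- function(field) unname(vapply(tdef, `[[`, 0, field)[cells$type])
  n <- ncells(cells)
  cells$rate_prolif <- if (n) pick("prolif_rate") else numeric(0)
  cells$rate_apop <- if (n) pick("apop_rate") else numeric(0)
  cells$rate_necrosis <- if (n) pick("necrosis_rate") else numeric(0)
  cells$speed <- if (n) pick("motility_speed") else numeric(0)
  cells
}

# Vectorized MOA application across the population: recompute current
# rates from base rates and the damage matrix. Same math as apply_moas()
# per cell; idempotent because rates are rebuilt from base each call.
apply_moas_population <- function(cells) {
  cells <- reset_rates(cells)
  n <- ncells(cells)
  if (!n || !length(cells$pd_substrates)) return(cells)
  for (tix in unique(cells$type)) {
    tdef <- cells$types[[tix]]
    sel <- cells$type == tix
    for (s in cells$pd_substrates) {
      moa <- tdef$moa[[s]]
      if (is.null(moa)) next
      D <- cells$D[sel, s]
      for (nm in names(moa)) {
        e <- moa[[nm]]
        if (nm == "necrosis") {
          cells$rate_necrosis[sel] <- cells$rate_necrosis[sel] +
            e$saturation_rate * hill_fraction(D, e$EC50, e$hill_power)
        } else {
          b <- switch(nm, prolif = tdef$prolif_rate, apop = tdef$apop_rate,
                      motility = tdef$motility_speed)
          f <- hill_factor(D, e$EC50, e$hill_power, e$saturation_rate / b)
          if (nm == "prolif") cells$rate_prolif[sel] <- cells$rate_prolif[sel] * f
          if (nm == "apop") cells$rate_apop[sel] <- cells$rate_apop[sel] * f
          if (nm == "motility") cells$speed[sel] <- cells$speed[sel] * f
        }
      }
    }
  }
  cells
}

# Keep only the cells flagged TRUE.
subset_cells <- function(cells, keep) {
  for (f in c("id", "x", "y", "type", "theta", "rate_prolif", "rate_apop",
              "rate_necrosis", "speed"))
    cells[[f]] <- cells[[f]][keep]
  cells$A <- cells$A[keep, , drop = FALSE]
  cells$D <- cells$D[keep, , drop = FALSE]
  cells
}

#' Division, apoptosis and necrosis over one phenotype step
#'
#' Competing risks are resolved by sampling an exponential waiting time
#' per risk from the cell's current rates and taking the earliest event
#' inside the step (unbiased for small steps). Daughters are placed one
#' radius from the parent at a uniform random angle, inherit the parent's
#' motility direction, and split or copy the internalized pools according
#' to each substrate's damage model: concentration-based (`AUC`) pools
#' and damage are intensive and are inherited by both daughters;
#' amount-based (`AUC_amount`) pools are split equally. Dead cells are
#' removed immediately.
#'
#' @param cells A [cell_population()].
#' @param dt Phenotype step (min, > 0).
#' @param domain List with `x_min`, `x_max`, `y_min`, `y_max` (um) used to
#'   clamp daughter positions.
#' @return A list with the updated `cells` and an `events` list
#'   (`n_division`, `n_apoptosis`, `n_necrosis`).
#' @export
phenotype_step <- function(cells, dt, domain = NULL) {
  stopifnot(inherits(cells, "cell_population"), dt > 0)
  n <- ncells(cells)
  ev <- list(n_division = 0L, n_apoptosis = 0L, n_necrosis = 0L)
  if (!n) return(list(cells = cells, events = ev))
  # fixed draw order: three uniform vectors, then division angles
  t_div <- -log(stats::runif(n)) / cells$rate_prolif
  t_apop <- -log(stats::runif(n)) / cells$rate_apop
  t_necr <- -log(stats::runif(n)) / cells$rate_necrosis
  t_min <- pmin(t_div, t_apop, t_necr)
  event <- t_min <= dt
  kind <- integer(n) # 1 division, 2 apoptosis, 3 necrosis
  kind[event & t_min == t_div] <- 1L
  kind[event & t_min == t_apop] <- 2L
  kind[event & t_min == t_necr] <- 3L
  divides <- which(kind == 1L)
  dies <- kind %in% c(2L, 3L)
  ev$n_division <- length(divides)
  ev$n_apoptosis <- sum(kind == 2L)
  ev$n_necrosis <- sum(kind == 3L)
  if (length(divides)) {
    ang <- stats::runif(length(divides), 0, 2 * pi)
    radius <- unname(vapply(cells$types, `[[`, 0, "radius")[cells$type[divides]])
    nx <- cells$x[divides] + radius * cos(ang)
    ny <- cells$y[divides] + radius * sin(ang)
    if (!is.null(domain)) {
      nx <- pmin(pmax(nx, domain$x_min), domain$x_max)
      ny <- pmin(pmax(ny, domain$y_min), domain$y_max)
    }
    # split amount-based pools in the parents before copying
    for (k in seq_along(cells$pd_substrates)) {
      s <- cells$pd_substrates[[k]]
      for (tix in unique(cells$type[divides])) {
        pdp <- cells$types[[tix]]$pd[[s]]
        if (!is.null(pdp) && pdp$damage_model == "AUC_amount") {
          rows <- divides[cells$type[divides] == tix]
          cells$A[rows, k] <- cells$A[rows, k] / 2
          cells$D[rows, k] <- cells$D[rows, k] / 2
        }
      }
    }
    m <- length(divides)
    cells$id <- c(cells$id, seq.int(cells$next_id, length.out = m))
    cells$next_id <- cells$next_id + m
    cells$x <- c(cells$x, nx)
    cells$y <- c(cells$y, ny)
    cells$type <- c(cells$type, cells$type[divides])
    cells$theta <- c(cells$theta, cells$theta[divides])
    cells$A <- rbind(cells$A, cells$A[divides, , drop = FALSE])
    cells$D <- rbind(cells$D, cells$D[divides, , drop = FALSE])
    cells$rate_prolif <- c(cells$rate_prolif, cells$rate_prolif[divides])
    cells$rate_apop <- c(cells$rate_apop, cells$rate_apop[divides])
    cells$rate_necrosis <- c(cells$rate_necrosis, cells$rate_necrosis[divides])
    cells$speed <- c(cells$speed, cells$speed[divides])
    dies <- c(dies, rep(FALSE, m))
  }
  if (any(dies)) cells <- subset_cells(cells, !dies)
  list(cells = cells, events = ev)
}

#' Motility and volume exclusion over one mechanics step
#'
#' Motile cells take a persistent random-walk step: the heading is
#' re-drawn with probability `dt / persistence_time`, then the cell moves
#' `speed * dt` along it. Overlapping pairs are then pushed apart along
#' their axis by a linear repulsion relaxation (displacement capped at
#' half the overlap), and positions are clamped to the domain.
#'
#' @param cells A [cell_population()].
#' @param dt Mechanics step (min, > 0).
#' @param domain List with `x_min`, `x_max`, `y_min`, `y_max` (um).
#' @param repulsion Relaxation rate of the overlap spring (1/min).
#' @return The updated population.
#' @export
mechanics_step <- function(cells, dt, domain, repulsion = 1) {
  stopifnot(inherits(cells, "cell_population"), dt > 0)
  n <- ncells(cells)
  if (!n) return(cells)
  tau <- unname(vapply(cells$types, `[[`, 0, "persistence_time")[cells$type])
  turn <- stats::runif(n) < pmin(dt / tau, 1)
  if (any(turn)) cells$theta[turn] <- stats::runif(sum(turn), 0, 2 * pi)
  step_len <- cells$speed * dt
  cells$x <- cells$x + step_len * cos(cells$theta)
  cells$y <- cells$y + step_len * sin(cells$theta)
  radius <- unname(vapply(cells$types, `[[`, 0, "radius")[cells$type])
  res <- relax_overlaps_cpp(cells$x, cells$y, radius, repulsion, dt,
                            domain$x_min, domain$x_max,
                            domain$y_min, domain$y_max)
  cells$x <- res$x
  cells$y <- res$y
  cells
}

#' 2D confluence of a population
#'
#' Proportion of the rectangular domain covered by cell cross-sections,
#' `sum_i pi r_i^2 / area`, capped at 1. Overlaps are not subtracted; the
#' measure is the standard summed-footprint proxy used for dose
#' triggering.
#'
#' @param cells A [cell_population()].
#' @param domain List with `x_min`, `x_max`, `y_min`, `y_max` (um).
#' @return Proportion in \[0, 1\].
#' @export
confluence <- function(cells, domain) {
  stopifnot(inherits(cells, "cell_population"))
  area <- (domain$x_max - domain$x_min) * (domain$y_max - domain$y_min)
  if (!ncells(cells)) return(0)
  radius <- vapply(cells$types, `[[`, 0, "radius")[cells$type]
  min(1, sum(pi * radius^2) / area)
}

#' Color cells by damage from up to two substrates
#'
#' Maps damage pairs, normalized by their EC50-scale saturating fraction
#' `s = (D/EC50) / (1 + D/EC50)`, through a fixed bilinear two-channel
#' colormap: no damage maps to light grey, saturating damage from the
#' first substrate to red, from the second to blue, and from both to dark
#' purple. Deterministic and monotone along each channel.
#'
#' @param D1,D2 Damage values (vectors); `D2` may be `NULL` when only one
#'   substrate is displayed.
#' @param EC50_1,EC50_2 The EC50s used for normalization.
#' @return A matrix with columns `r`, `g`, `b` in \[0, 1\].
#' @export
damage_coloring <- function(D1, EC50_1, D2 = NULL, EC50_2 = NULL) {
  s1 <- (D1 / EC50_1) / (1 + D1 / EC50_1)
  s2 <- if (is.null(D2)) rep(0, length(D1))
        else (D2 / EC50_2) / (1 + D2 / EC50_2)
  corner <- function(r, g, b) c(r = r, g = g, b = b)
  c00 <- corner(0.8, 0.8, 0.8)  # undamaged
  c10 <- corner(0.9, 0.1, 0.1)  # substrate 1 saturated
  c01 <- corner(0.1, 0.1, 0.9)  # substrate 2 saturated
  c11 <- corner(0.35, 0.0, 0.35)  # both saturated
  w00 <- (1 - s1) * (1 - s2); w10 <- s1 * (1 - s2)
  w01 <- (1 - s1) * s2; w11 <- s1 * s2
  cbind(r = w00 * c00[1] + w10 * c10[1] + w01 * c01[1] + w11 * c11[1],
        g = w00 * c00[2] + w10 * c10[2] + w01 * c01[2] + w11 * c11[2],
        b = w00 * c00[3] + w10 * c10[3] + w01 * c01[3] + w11 * c11[3])
}
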