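# Coarse-grained diffusion-limited aggregation of rod-shaped triple helices.
#
# A triple-helical design is reduced to a rigid rod of 1 nm spheres:
# adhesive modules contribute one sphere per triplet (proline-rich triplets
# rise ~1 nm each over three chains), driver modules round(n_triplets *
# 25/27) spheres (the lower ~0.9 nm per-triplet rise of low-Pro sequences).
# Rods stay axis-parallel and stick through lateral adhesive-adhesive
# contacts in full module register, which is what produces clean banding.

#' Coarse-grained rod model of a design
#'
#' @param design a banding-competent `collagen_design`, or `NULL` when the
#'   sphere counts are given directly.
#' @param driver_rise spheres per driver triplet (default 25/27, reproducing
#'   the 27-triplet -> 25-sphere mapping).
#' @param force build a rod for an incompetent design with a warning instead
#'   of an error.
#' @param n_adhesive length-2 integer, spheres in the N/C adhesive modules
#'   (direct construction).
#' @param n_driver driver sphere count (direct construction).
#' @param sticky length-2 character, sticky types of the N/C adhesives
#'   (`"P"`, `"R"`, `"E"`).
#' @return a `rod_model`: sphere labels (`adhesiveN`/`driver`/`adhesiveC`),
#'   per-sphere sticky type, rod length in nm (= sphere count; diameter 1 nm).
#' @export
rod_from_design <- function(design = NULL, driver_rise = 25 / 27, force = FALSE,
                            n_adhesive = NULL, n_driver = NULL, sticky = NULL) {
  if (!is.null(design)) {
    v <- classify_banding(design)
    if (!v$competent) {
      msg <- sprintf("design %s is not banding-competent (%s)", design$name, v$reason)
      if (force) warning(msg) else stop(msg, "; use force = TRUE to override")
    }
    fl <- design_flanks(design)
    n_adhesive <- c(fl$n_module$n_triplets, fl$c_module$n_triplets)
    drv <- sum(vapply(driver_modules(design), `[[`, integer(1), "n_triplets"))
    n_driver <- as.integer(round(drv * driver_rise))
    sticky <- c(fl$n_module$kind, fl$c_module$kind)
    name <- design$name
  } else {
    stopifnot(length(n_adhesive) == 2L, length(sticky) == 2L, n_driver >= 0)
    name <- "rod"
  }
  labels <- c(rep("adhesiveN", n_adhesive[1]), rep("driver", n_driver),
              rep("adhesiveC", n_adhesive[2]))
  type <- c(rep(sticky[1], n_adhesive[1]), rep(NA_character_, n_driver),
            rep(sticky[2], n_adhesive[2]))
  structure(list(name = name, labels = labels, type = type,
                 n_adhesive = as.integer(n_adhesive),
                 n_driver = as.integer(n_driver),
                 n_spheres = length(labels), length_nm = length(labels),
                 diameter_nm = 1,
                 period = as.integer(n_adhesive[1] + n_driver)),
            class = "rod_model")
}

#' @export
print.rod_model <- function(x, ...) {
  cat(sprintf("<rod_model> %s: (%d adhesive, %d driver, %d adhesive) = %d spheres, period %d\n",
              x$name, x$n_adhesive[1], x$n_driver, x$n_adhesive[2],
              x$n_spheres, x$period))
  invisible(x)
}

#' Anisotropic diffusion step probabilities of a rod
#'
#' A cylinder of length L and diameter D meets viscous resistance
#' proportional to its cross-section in the direction of motion, so axial
#' and lateral step probabilities satisfy P_axial / P_lateral = 4L / (pi D).
#'
#' @param rod a `rod_model`.
#' @return list with `p_axial`, `p_lateral` (summing to 1) and `ratio`.
#' @export
step_probabilities <- function(rod) {
  ratio <- 4 * rod$length_nm / (pi * rod$diameter_nm)
  structure(list(ratio = ratio, p_axial = ratio / (1 + ratio),
                 p_lateral = 1 / (1 + ratio)),
            class = "step_probabilities")
}

#' Sample diffusion step classes for a rod
#'
#' Draws `n_steps` axial/lateral decisions with the walker's own decision
#' rule, for checking that the empirical step-frequency ratio reproduces
#' 4L/(pi D).
#'
#' @param rod a `rod_model`.
#' @param n_steps number of steps to draw.
#' @param seed RNG seed.
#' @return list with `axial`, `lateral` counts and their `ratio`.
#' @export
sample_rod_steps <- function(rod, n_steps = 1e6, seed = 1L) {
  p <- step_probabilities(rod)$p_axial
  counts <- with_seed(seed, cpp_step_counts(p, n_steps))
  list(axial = counts[1], lateral = counts[2], ratio = counts[1] / counts[2])
}

#' DLA simulation configuration
#'
#' @param n_rods rods to place (including the seed rod).
#' @param seed RNG seed.
#' @param launch_margin launch circle radius = aggregate radius + margin (nm).
#' @param kill_factor walkers beyond `kill_factor` times the launch radius
#'   (or equivalent axial excursion) are relaunched.
#' @param max_steps relaunch a walker after this many steps.
#' @param min_contacts adhesive contact spheres required to stick; default
#'   one full adhesive module (full register).
#' @param allowed_pairs sticky-type pairs that can bind; default P-P and R-E.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_rods = 300L, seed = 1L, launch_margin = 5,
                       kill_factor = 3, max_steps = 1e6,
                       min_contacts = NULL,
                       allowed_pairs = list(c("P", "P"), c("R", "E"))) {
  stopifnot(n_rods >= 1L, launch_margin > 0, kill_factor > 1)
  structure(list(n_rods = as.integer(n_rods), seed = seed,
                 launch_margin = launch_margin, kill_factor = kill_factor,
                 max_steps = max_steps, min_contacts = min_contacts,
                 allowed_pairs = allowed_pairs),
            class = "sim_config")
}

sticky_codes <- c(P = 0L, R = 1L, E = 2L)

allow_matrix <- function(allowed_pairs) {
  m <- matrix(FALSE, 3, 3, dimnames = list(names(sticky_codes), names(sticky_codes)))
  for (p in allowed_pairs) {
    m[p[1], p[2]] <- TRUE
    m[p[2], p[1]] <- TRUE
  }
  m
}

#' Grow a fiber aggregate by diffusion-limited aggregation
#'
#' A seed rod is placed at the origin; further rods are launched on a circle
#' outside the aggregate and random-walk on the hexagonal lattice (axial
#' steps 4L/(pi D) more probable than lateral) until their adhesive spheres
#' contact aggregate adhesive spheres of compatible type in full module
#' register. Deterministic given `config$seed`.
#'
#' @param rod a `rod_model`.
#' @param config a [sim_config()].
#' @return a `dla_aggregate`: site table (rod, sphere, lattice q/r/z,
#'   Cartesian x/y in nm, label, sticky type), rod base positions, contact
#'   edges, the rod and config, and walk statistics.
#' @export
run_dla <- function(rod, config = sim_config()) {
  type_code <- ifelse(is.na(rod$type), -1L, sticky_codes[rod$type])
  min_c <- config$min_contacts %||% min(rod$n_adhesive)
  res <- with_seed(config$seed,
    cpp_run_dla(as.integer(type_code), rod$period, config$n_rods,
                step_probabilities(rod)$p_axial, config$launch_margin,
                config$kill_factor, config$max_steps, as.integer(min_c),
                allow_matrix(config$allowed_pairs)))
  bases <- res$bases
  L <- rod$n_spheres
  n <- nrow(bases)
  sites <- data.frame(
    rod = rep(seq_len(n), each = L),
    sphere = rep(seq_len(L), times = n),
    q = rep(bases[, 1], each = L),
    r = rep(bases[, 2], each = L),
    z = rep(bases[, 3], each = L) + rep(seq_len(L) - 1L, times = n),
    label = rep(rod$labels, times = n),
    type = rep(rod$type, times = n))
  sites$x <- sites$q + 0.5 * sites$r
  sites$y <- sqrt(3) / 2 * sites$r
  structure(list(sites = sites, bases = bases, rod = rod, config = config,
                 contacts = data.frame(rod_i = res$edges[, 1],
                                       rod_j = res$edges[, 2]),
                 stats = list(total_steps = res$total_steps,
                              axial_steps = res$axial_steps,
                              lateral_steps = res$lateral_steps,
                              relaunches = res$relaunches)),
            class = "dla_aggregate")
}

#' @export
print.dla_aggregate <- function(x, ...) {
  d <- fiber_dimensions(x)
  cat(sprintf("<dla_aggregate> %d rods x %d spheres; length %.0f nm, thickness %.1f nm\n",
              nrow(x$bases), x$rod$n_spheres, d$length_nm, d$thickness_nm))
  invisible(x)
}

#' Check aggregate invariants
#'
#' Verifies that no lattice site is double-occupied, that mass is conserved
#' (placed rods x spheres per rod = occupied sites), that every non-seed rod
#' has at least one sticking contact, and that the contact graph is
#' connected.
#'
#' @param agg a `dla_aggregate`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
check_aggregate <- function(agg) {
  key <- paste(agg$sites$q, agg$sites$r, agg$sites$z)
  if (anyDuplicated(key)) stop("lattice site double-occupied")
  n <- nrow(agg$bases)
  if (nrow(agg$sites) != n * agg$rod$n_spheres) stop("mass not conserved")
  if (n > 1L) {
    touched <- union(agg$contacts$rod_i, agg$contacts$rod_j)
    if (!all(seq(2L, n) %in% agg$contacts$rod_i)) {
      stop("non-seed rod without a sticking contact")
    }
    # BFS connectivity over the contact graph
    adj <- split(c(agg$contacts$rod_j, agg$contacts$rod_i),
                 c(agg$contacts$rod_i, agg$contacts$rod_j))
    seen <- logical(n); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[as.character(v)]]
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (!all(seen)) stop("contact graph not connected")
    invisible(touched)
  }
  invisible(TRUE)
}

#' Axial packing-density profile of an aggregate
#'
#' Counts occupied sites per 1 nm z-bin, split into adhesive and driver
#' spheres; under full-register sticking the profile is periodic with period
#' equal to one adhesive plus one driver module.
#'
#' @param agg a `dla_aggregate`.
#' @return data.frame with columns `z`, `n`, `n_adhesive`, `n_driver`.
#' @export
axial_density <- function(agg) {
  s <- agg$sites
  zr <- seq(min(s$z), max(s$z))
  n <- tabulate(s$z - zr[1] + 1L, nbins = length(zr))
  adh <- s$label != "driver"
  n_a <- tabulate(s$z[adh] - zr[1] + 1L, nbins = length(zr))
  data.frame(z = zr, n = n, n_adhesive = n_a, n_driver = n - n_a)
}

#' Axial density as a band trace
#'
#' Converts the axial packing-density profile into a `band_trace` for the
#' period estimators; optionally trims to the central fraction of the fiber
#' where the banding contrast is strongest.
#'
#' @param agg a `dla_aggregate`.
#' @param central fraction of the axial extent to keep, centered (default 1,
#'   the whole fiber).
#' @return a `band_trace` (1 nm sampling).
#' @export
axial_band_trace <- function(agg, central = 1) {
  dens <- axial_density(agg)
  n <- nrow(dens)
  if (central < 1) {
    k <- round(n * (1 - central) / 2)
    dens <- dens[seq(k + 1L, n - k), ]
  }
  band_trace(dens$n, dx_nm = 1, source = "simulated")
}

#' Fiber dimensions of an aggregate
#'
#' Length is the axial extent of occupied sites; thickness the mean, over
#' occupied z-bins, of the lateral bounding-circle diameter (max pairwise
#' xy distance plus one sphere diameter).
#'
#' @param agg a `dla_aggregate`.
#' @return list with `length_nm`, `thickness_nm`, `aspect_ratio`.
#' @export
fiber_dimensions <- function(agg) {
  s <- agg$sites
  len <- max(s$z) - min(s$z) + 1
  diam_bin <- vapply(split(seq_len(nrow(s)), s$z), function(i) {
    if (length(i) == 1L) return(1)
    xy <- cbind(s$x[i], s$y[i])
    max(stats::dist(xy)) + 1
  }, numeric(1))
  th <- mean(diam_bin)
  list(length_nm = len, thickness_nm = th, aspect_ratio = len / th)
}

# thickness profile over thirds of the axial extent (taper diagnostics)
thickness_thirds <- function(agg) {
  s <- agg$sites
  zr <- range(s$z)
  cut1 <- zr[1] + (zr[2] - zr[1]) / 3
  cut2 <- zr[1] + 2 * (zr[2] - zr[1]) / 3
  seg <- ifelse(s$z < cut1, 1L, ifelse(s$z < cut2, 2L, 3L))
  vapply(1:3, function(k) {
    i <- which(seg == k)
    if (!length(i)) return(NA_real_)
    sub <- agg
    sub$sites <- s[i, ]
    fiber_dimensions(sub)$thickness_nm
  }, numeric(1))
}

#' Ensemble of DLA simulations over rod counts
#'
#' Repeats the simulation `reps` times for each rod count with seeds derived
#' from a master seed, and summarises fiber dimensions per count. The
#' weighted average weights each replicate by its placed-rod count (within a
#' count group this equals the simple mean, which is also reported).
#'
#' @param rod a `rod_model`.
#' @param rod_counts rods per simulation (default the full ladder
#'   50...3000).
#' @param reps replicates per count (default 100).
#' @param seed master seed.
#' @param config template [sim_config()]; `n_rods` and `seed` are set per run.
#' @return list with `runs` (per-run dimensions) and `summary` (per-count
#'   mean/sd of length, thickness and aspect ratio).
#' @export
ensemble_run <- function(rod, rod_counts = c(50, 100, 300, 600, 1000, 1500, 3000),
                         reps = 100L, seed = 1L, config = sim_config()) {
  stopifnot(reps >= 1L)
  runs <- list()
  for (nc in rod_counts) {
    for (rep in seq_len(reps)) {
      cfg <- config
      cfg$n_rods <- as.integer(nc)
      cfg$seed <- derive_seed(seed, nc, rep)
      agg <- run_dla(rod, cfg)
      d <- fiber_dimensions(agg)
      runs[[length(runs) + 1L]] <- data.frame(
        n_rods = nc, rep = rep, length_nm = d$length_nm,
        thickness_nm = d$thickness_nm, aspect_ratio = d$aspect_ratio)
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$n_rods), function(g) {
    w <- g$n_rods / sum(g$n_rods)
    data.frame(n_rods = g$n_rods[1],
               mean_length_nm = mean(g$length_nm), sd_length_nm = sd(g$length_nm),
               wmean_length_nm = sum(w * g$length_nm),
               mean_thickness_nm = mean(g$thickness_nm),
               sd_thickness_nm = sd(g$thickness_nm),
               wmean_thickness_nm = sum(w * g$thickness_nm),
               mean_aspect = mean(g$aspect_ratio), sd_aspect = sd(g$aspect_ratio))
  }))
  summ <- summ[order(summ$n_rods), ]
  rownames(summ) <- NULL
  list(runs = runs, summary = summ)
}

#' Render a 2-D projection of an aggregate
#'
#' Projects site occupancy along the y axis onto an (x, z) pixel grid;
#' pixel values are occupancy normalised to [0, 1]. `invert = TRUE` swaps
#' the contrast convention (gap-dark/overlap-light as in negative-stain TEM
#' versus the opposite in cryoET).
#'
#' @param agg a `dla_aggregate`.
#' @param invert flip the grayscale.
#' @return a `fiber_image`: numeric matrix (rows = x, cols = z) in [0, 1].
#' @export
render_projection <- function(agg, invert = FALSE) {
  s <- agg$sites
  xi <- round(s$x - min(s$x)) + 1L
  zi <- s$z - min(s$z) + 1L
  img <- matrix(0, nrow = max(xi), ncol = max(zi))
  for (i in seq_along(xi)) img[xi[i], zi[i]] <- img[xi[i], zi[i]] + 1
  img <- img / max(img)
  if (invert) img <- 1 - img
  structure(img, class = "fiber_image", invert = invert)
}

#' Invert the contrast of a rendered projection
#'
#' @param img a `fiber_image`.
#' @return the image with grayscale flipped; applying it twice returns the
#'   original.
#' @export
invert_image <- function(img) {
  out <- 1 - unclass(img)
  structure(out, class = "fiber_image", invert = !isTRUE(attr(img, "invert")))
}

#' Column-mean intensity trace of a projection
#'
#' @param img a `fiber_image`.
#' @return a `band_trace` of mean intensity per z column (1 nm sampling).
#' @export
projection_trace <- function(img) {
  band_trace(colMeans(unclass(img)), dx_nm = 1, source = "simulated")
}

#' Export aggregate coordinates
#'
#' Writes the site table as CSV (`rod, sphere, x, y, z, label`) or an
#' XYZ-style coordinate file (one pseudo-atom per sphere; `A` adhesive,
#' `D` driver).
#'
#' @param agg a `dla_aggregate`.
#' @param file output path.
#' @param format `"csv"` or `"xyz"`.
#' @return `file`, invisibly.
#' @export
write_aggregate <- function(agg, file, format = c("csv", "xyz")) {
  format <- match.arg(format)
  s <- agg$sites
  if (format == "csv") {
    write.csv(s[, c("rod", "sphere", "x", "y", "z", "label")], file,
              row.names = FALSE)
  } else {
    el <- ifelse(s$label == "driver", "D", "A")
    lines <- c(nrow(s), sprintf("aggregate of %d rods", nrow(agg$bases)),
               sprintf("%s %.3f %.3f %.3f", el, s$x, s$y, s$z))
    writeLines(lines, file)
  }
  invisible(file)
}
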