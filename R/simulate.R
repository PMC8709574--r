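#' Simulate a swim path with a named search strategy's signature
#'
#' Seeded generator producing trajectories whose geometry sits well inside
#' the classification thresholds for the requested strategy:
#' * `Tt` - wall-following noise process in the outer ring;
#' * `RS` - reflected persistent random walk over the inner area;
#' * `Sc` - inner-area walk visiting quadrant-balanced waypoints through
#'   the pool center;
#' * `Ch` - constant-radius circling at the platform's orbit radius;
#' * `DS` - corridor-constrained zigzag toward the platform;
#' * `FS` - approach followed by a confined wander inside the focal zone;
#' * `DSw` - near-straight swim from release point to platform.
#'
#' Paths are sampled at 0.1-s steps at a nominal swim speed of 18 cm/s.
#'
#' @param strategy One of `"Tt"`, `"RS"`, `"Sc"`, `"Ch"`, `"DS"`, `"FS"`,
#'   `"DSw"`.
#' @param geometry A [pool_geometry()].
#' @param params Optional overrides: `dt`, `speed`, `duration`,
#'   `start_position` (compass label; sampled if `NULL`).
#' @param seed Integer seed; the same seed and parameters reproduce the
#'   path exactly.
#' @return A list with `trial` (a [swim_trial()]) and `ground_truth`
#'   (generator name, intended strategy, seed, parameters).
#' @export
gen_swim_path <- function(strategy, geometry = pool_geometry(),
                          params = list(), seed = 1) {
  if (!strategy %in% c("Tt", "RS", "Sc", "Ch", "DS", "FS", "DSw")) {
    stop(sprintf("unknown strategy '%s'", strategy), call. = FALSE)
  }
  p <- utils::modifyList(
    list(dt = 0.1, speed = 18, duration = 40, start_position = NULL),
    params
  )
  with_seed(seed, {
    sp <- p$start_position %||% sample(c("N", "E", "S", "W"), 1)
    start <- start_point(geometry, sp)
    xy <- switch(strategy,
      Tt = sim_wall_follow(start, geometry, p),
      RS = sim_random_walk(start, geometry, p),
      Sc = sim_scanning(start, geometry, p),
      Ch = sim_chaining(start, geometry, p),
      DS = sim_directed_search(start, geometry, p),
      FS = sim_focal_search(start, geometry, p),
      DSw = sim_direct_swim(start, geometry, p)
    )
    # keep jittered points inside the pool
    r <- sqrt(xy[, 1]^2 + xy[, 2]^2)
    over <- r > geometry$pool_radius - 0.2
    if (any(over)) {
      sc <- (geometry$pool_radius - 0.2) / r[over]
      xy[over, ] <- xy[over, ] * sc
    }
    samples <- data.frame(t = (seq_len(nrow(xy)) - 1) * p$dt,
                          x = xy[, 1], y = xy[, 2])
    trial <- swim_trial(samples, geometry,
                        trial_id = sprintf("%s_seed%d", strategy, seed),
                        start_position = sp)
    list(trial = trial,
         ground_truth = list(generator = "gen_swim_path",
                             strategy = strategy, seed = seed, params = p))
  })
}

unit2 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0) else v / n
}

# resample a polyline at constant arc-length steps, with positional jitter
polyline_walk <- function(verts, step, jitter = 0) {
  seg <- sqrt(rowSums(diff(verts)^2))
  arc <- c(0, cumsum(seg))
  grid <- seq(0, arc[length(arc)], by = step)
  x <- stats::approx(arc, verts[, 1], xout = grid)$y
  y <- stats::approx(arc, verts[, 2], xout = grid)$y
  if (jitter > 0) {
    n <- length(x)
    x <- x + c(0, rnorm(n - 1, 0, jitter))
    y <- y + c(0, rnorm(n - 1, 0, jitter))
  }
  cbind(x, y)
}

sim_wall_follow <- function(start, geom, p) {
  nt <- round(p$duration / p$dt)
  rr <- geom$pool_radius - geom$outer_ring_width / 2
  lo <- geom$pool_radius - geom$outer_ring_width + 1.5
  hi <- geom$pool_radius - 0.5
  dir <- sample(c(-1, 1), 1)
  omega <- p$speed / rr * p$dt
  theta <- atan2(start[2], start[1]) +
    cumsum(c(0, rnorm(nt - 1, dir * omega, 0.015)))
  r <- numeric(nt)
  r[1] <- sqrt(sum(start^2))
  for (i in 2:nt) {
    r[i] <- min(max(rr + 0.9 * (r[i - 1] - rr) + rnorm(1, 0, 0.4), lo), hi)
  }
  cbind(r * cos(theta), r * sin(theta))
}

sim_random_walk <- function(start, geom, p) {
  nt <- round(p$duration / p$dt)
  rmax <- geom$pool_radius - geom$outer_ring_width - 4
  step <- p$speed * p$dt
  xy <- matrix(0, nt, 2)
  xy[1, ] <- start
  heading <- atan2(-start[2], -start[1]) # head inward first
  for (i in 2:nt) {
    heading <- heading + rnorm(1, 0, 0.7)
    cand <- xy[i - 1, ] + step * c(cos(heading), sin(heading))
    if (sqrt(sum(cand^2)) > rmax) {
      heading <- atan2(-xy[i - 1, 2], -xy[i - 1, 1]) + rnorm(1, 0, 0.3)
      cand <- xy[i - 1, ] + step * c(cos(heading), sin(heading))
      if (sqrt(sum(cand^2)) > rmax) cand <- cand * rmax / sqrt(sum(cand^2))
    }
    xy[i, ] <- cand
  }
  xy
}

sim_scanning <- function(start, geom, p) {
  cycles <- 3
  verts <- matrix(start, 1)
  for (cy in seq_len(cycles)) {
    for (q in sample(4)) {
      ang <- geom$quadrant_axes + (q - 0.5) * pi / 2 + runif(1, -pi / 6, pi / 6)
      rad <- runif(1, 35, 60)
      thru <- runif(1, 0, 2 * pi)
      dctr <- runif(1, 0, 8)
      verts <- rbind(verts,
                     dctr * c(cos(thru), sin(thru)),
                     rad * c(cos(ang), sin(ang)))
    }
  }
  polyline_walk(verts, p$speed * p$dt, jitter = 0.3)
}

sim_chaining <- function(start, geom, p) {
  orbit <- sqrt(sum(geom$platform_center^2))
  step <- p$speed * p$dt
  th0 <- atan2(start[2], start[1])
  r0 <- sqrt(sum(start^2))
  n_app <- max(1, ceiling((r0 - orbit) / step))
  approach <- cbind(seq(r0, orbit, length.out = n_app + 1) * cos(th0),
                    seq(r0, orbit, length.out = n_app + 1) * sin(th0))
  dir <- sample(c(-1, 1), 1)
  omega <- p$speed / orbit * p$dt
  revs <- 2.2
  nt <- round(revs * 2 * pi / omega)
  theta <- th0 + cumsum(rnorm(nt, dir * omega, 0.01))
  r <- numeric(nt)
  r[1] <- orbit
  for (i in 2:nt) {
    r[i] <- min(max(orbit + 0.9 * (r[i - 1] - orbit) + rnorm(1, 0, 0.5),
                    orbit - 6), orbit + 6)
  }
  rbind(approach, cbind(r * cos(theta), r * sin(theta)))
}

sim_directed_search <- function(start, geom, p) {
  target <- geom$platform_center
  step <- p$speed * p$dt
  amp <- 70 * pi / 180
  period <- 0.8
  phi <- runif(1, 0, 2 * pi)
  xy <- matrix(start, 1)
  pos <- start
  for (i in seq_len(1200)) {
    if (sqrt(sum((pos - target)^2)) <= geom$platform_diameter / 2) break
    bearing <- atan2(target[2] - pos[2], target[1] - pos[1])
    heading <- bearing + amp * sin(2 * pi * (i * p$dt) / period + phi) +
      rnorm(1, 0, 0.05)
    pos <- pos + step * c(cos(heading), sin(heading))
    xy <- rbind(xy, pos)
  }
  xy
}

sim_focal_search <- function(start, geom, p) {
  pc <- geom$platform_center
  step <- p$speed * p$dt
  zone_r <- geom$focal_zone_diameter / 2 - 2
  xy <- matrix(start, 1)
  pos <- start
  # approach leg
  for (i in seq_len(1200)) {
    if (sqrt(sum((pos - pc)^2)) <= zone_r - 3) break
    bearing <- atan2(pc[2] - pos[2], pc[1] - pos[1])
    pos <- pos + step * c(cos(bearing + rnorm(1, 0, 0.08)), sin(bearing + rnorm(1, 0, 0.08)))
    xy <- rbind(xy, pos)
  }
  # confined wander
  heading <- runif(1, 0, 2 * pi)
  nt <- round(25 / p$dt)
  for (i in seq_len(nt)) {
    d <- sqrt(sum((pos - pc)^2))
    heading <- if (d > zone_r - 3) {
      atan2(pc[2] - pos[2], pc[1] - pos[1]) + rnorm(1, 0, 0.3)
    } else {
      heading + rnorm(1, 0, 1.2)
    }
    pos <- pos + step * c(cos(heading), sin(heading))
    d <- sqrt(sum((pos - pc)^2))
    if (d > zone_r) pos <- pc + (pos - pc) * zone_r / d
    xy <- rbind(xy, pos)
  }
  xy
}

sim_direct_swim <- function(start, geom, p) {
  target <- geom$platform_center
  step <- p$speed * p$dt
  xy <- matrix(start, 1)
  pos <- start
  for (i in seq_len(600)) {
    if (sqrt(sum((pos - target)^2)) <= geom$platform_diameter / 2) break
    bearing <- atan2(target[2] - pos[2], target[1] - pos[1])
    heading <- bearing + rnorm(1, 0, 0.12)
    pos <- pos + step * c(cos(heading), sin(heading))
    xy <- rbind(xy, pos)
  }
  xy
}

#' Simulate a coupled pair of LFP channels with known coherence
#'
#' Linear mixing model `x = s + n1`, `y = alpha * s + n2`: a shared
#' band-limited Gaussian source plus independent white noise in each
#' channel. The source is shaped in the frequency domain (coefficients
#' outside `source_band` zeroed, half-open `[lo, hi)` to match the band
#' convention) and scaled so that the in-band source-to-noise power ratio
#' per channel equals `snr_a` and `snr_b`. The magnitude-squared coherence
#' then has the closed form
#' `snr_a / (1 + snr_a) * snr_b / (1 + snr_b)` inside the band and zero
#' outside, which is attached as ground truth.
#'
#' @param source_band Numeric (lo, hi) in Hz.
#' @param snr_a,snr_b In-band source/noise power ratios (> 0).
#' @param alpha Coupling gain of the source into channel b; `alpha = 0`
#'   yields independent channels.
#' @param fs Sampling rate, Hz (>= 200).
#' @param duration Recording duration, s (>= 2).
#' @param seed Integer seed.
#' @return A list with `a`, `b` ([lfp_recording()]s) and `ground_truth`
#'   (`inband_coherence`, `source_band`, model parameters).
#' @export
gen_lfp_pair <- function(source_band = c(4, 12), snr_a = 1, snr_b = 1,
                         alpha = 1, fs = 1000, duration = 100, seed = 1) {
  if (fs < 200) stop("`fs` must be at least 200 Hz", call. = FALSE)
  if (duration < 2) stop("`duration` must be at least 2 s", call. = FALSE)
  if (snr_a <= 0 || snr_b <= 0) stop("SNR values must be positive", call. = FALSE)
  lo <- source_band[1]
  hi <- source_band[2]
  if (lo <= 0 || hi <= lo || hi >= fs / 2) {
    stop("`source_band` must satisfy 0 < lo < hi < fs/2", call. = FALSE)
  }
  with_seed(seed, {
    n <- round(fs * duration)
    nyq <- fs / 2
    bw <- hi - lo
    W <- stats::fft(rnorm(n))
    f <- (0:(n - 1)) * fs / n
    fmir <- pmin(f, fs - f)
    W[!(fmir >= lo & fmir < hi)] <- 0
    s <- Re(stats::fft(W, inverse = TRUE)) / n
    target_var <- snr_a * bw / nyq # channel noise has unit variance over [0, nyq]
    s <- s * sqrt(target_var / stats::var(s))
    x <- s + rnorm(n)
    if (alpha == 0) {
      y <- rnorm(n)
      inband <- 0
    } else {
      n2_sd <- sqrt(alpha^2 * target_var * (nyq / bw) / snr_b)
      y <- alpha * s + n2_sd * rnorm(n)
      inband <- (snr_a / (1 + snr_a)) * (snr_b / (1 + snr_b))
    }
    list(
      a = lfp_recording(x, fs, "dHip"),
      b = lfp_recording(y, fs, "mPFC"),
      ground_truth = list(generator = "gen_lfp_pair",
                          inband_coherence = inband,
                          source_band = c(lo, hi), snr_a = snr_a,
                          snr_b = snr_b, alpha = alpha, fs = fs,
                          duration = duration, seed = seed)
    )
  })
}

#' Simulate a neuron reconstruction with known length and Sholl profile
#'
#' Builds a soma, a straight radial trunk, and `n_branches` straight
#' branches growing outward (within 60 degrees of the trunk direction) from
#' the trunk tip. Because every segment's distance to the soma is monotone,
#' the Sholl profile of the planned geometry has the closed form "count of
#' segments whose distance interval contains the radius", which is attached
#' as ground truth along with the exact total length.
#'
#' @param n_branches Number of branches at the trunk tip (>= 0).
#' @param trunk_length,branch_length Segment lengths in micrometers;
#'   `branch_length` is recycled across branches.
#' @param increment Radius increment of the ground-truth Sholl profile.
#' @param seed Integer seed.
#' @return A list with `tree` (a [neuron_tree()]) and `ground_truth`
#'   (`total_length`, `sholl` data frame, seed).
#' @export
gen_neuron_tree <- function(n_branches = 2, trunk_length = 50,
                            branch_length = 40, increment = 20, seed = 1) {
  if (n_branches < 0) stop("`n_branches` must be >= 0", call. = FALSE)
  if (trunk_length <= 0 || any(branch_length <= 0)) {
    stop("segment lengths must be positive", call. = FALSE)
  }
  n_branches <- as.integer(n_branches)
  bl <- rep_len(branch_length, max(n_branches, 1L))[seq_len(n_branches)]
  with_seed(seed, {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    tip <- u * trunk_length
    nodes <- data.frame(
      id = 1:2, type = c(1L, 3L),
      x = c(0, tip[1]), y = c(0, tip[2]), z = c(0, tip[3]),
      radius = c(2, 0.5), parent = c(-1L, 1L)
    )
    d1 <- trunk_length # branch segments start at the trunk tip
    dist_lo <- 0
    dist_hi <- trunk_length
    for (i in seq_len(n_branches)) {
      repeat {
        d <- rnorm(3)
        d <- d / sqrt(sum(d^2))
        if (sum(d * u) >= 0.5) break # outward cone keeps distances monotone
      }
      e <- tip + d * bl[i]
      nodes <- rbind(nodes, data.frame(id = 2L + i, type = 3L,
                                       x = e[1], y = e[2], z = e[3],
                                       radius = 0.5, parent = 2L))
      dist_lo <- c(dist_lo, d1)
      dist_hi <- c(dist_hi, sqrt(sum(e^2)))
    }
    extent <- max(dist_hi)
    radii <- increment * seq_len(ceiling(extent / increment))
    counts <- vapply(radii,
                     function(r) sum(dist_lo <= r & dist_hi > r), integer(1))
    list(
      tree = neuron_tree(nodes),
      ground_truth = list(generator = "gen_neuron_tree",
                          total_length = trunk_length + sum(bl),
                          sholl = data.frame(radius = radii,
                                             intersections = counts),
                          seed = seed)
    )
  })
}

#' Simulate a milestone score table with known maturity days
#'
#' Draws one set of base maturity days and applies `group_shift_days` to
#' the second group (matched construction), so that with `noise = 0` the
#' difference of group median maturity days equals the shift exactly.
#' Each animal scores below criterion before its onset day and at
#' criterion from the onset through P21, where the onset is chosen so the
#' rule's qualifying run ends exactly on the drawn maturity day. With
#' `noise > 0`, pre-onset days independently receive a spurious criterion
#' score with that probability, so the attached ground truth is exact only
#' for noise-free tables.
#'
#' @param n_per_group Animals per group (>= 1).
#' @param test_name Milestone test (must have a rule).
#' @param rule A [maturity_rule()]; defaults to the test's standard rule.
#' @param base_days Candidate maturity days the first group draws from.
#' @param group_shift_days Shift in days applied to the second group.
#' @param noise Probability of a spurious pre-onset success.
#' @param groups Length-2 character, group labels.
#' @param seed Integer seed.
#' @return A list with `table` (a [milestone_table()]) and `ground_truth`
#'   (data frame `animal_id`, `group`, `day`).
#' @export
gen_milestone_table <- function(n_per_group = 9,
                                test_name = "surface_righting",
                                rule = NULL, base_days = 5:9,
                                group_shift_days = 0, noise = 0,
                                groups = c("WT", "KO"), seed = 1) {
  if (n_per_group < 1) stop("`n_per_group` must be >= 1", call. = FALSE)
  rule <- rule %||% default_milestone_rules()[[test_name]]
  if (is.null(rule)) stop(sprintf("no rule for test '%s'", test_name), call. = FALSE)
  L <- rule$consecutive_days_required
  with_seed(seed, {
    base <- sample(base_days, n_per_group, replace = TRUE)
    truth <- data.frame(
      animal_id = c(sprintf("%s_%02d", groups[1], seq_len(n_per_group)),
                    sprintf("%s_%02d", groups[2], seq_len(n_per_group))),
      group = rep(groups, each = n_per_group),
      day = c(base, base + group_shift_days)
    )
    if (any(truth$day - L + 1 < 1) || any(truth$day > 21)) {
      stop("group shift places maturity runs outside P1-P21", call. = FALSE)
    }
    recs <- lapply(seq_len(nrow(truth)), function(i) {
      m <- truth$day[i]
      onset <- m - L + 1
      score <- ifelse(1:21 >= onset, rule$criterion, 0)
      if (noise > 0) {
        pre <- which(1:21 < onset)
        flip <- pre[runif(length(pre)) < noise]
        score[flip] <- rule$criterion
      }
      data.frame(animal_id = truth$animal_id[i], group = truth$group[i],
                 test_name = test_name, day = 1:21, score = score)
    })
    rules <- stats::setNames(list(rule), test_name)
    list(
      table = milestone_table(do.call(rbind, recs), rules),
      ground_truth = truth
    )
  })
}
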