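#' Specify a synthetic ground-truth scene
#'
#' A scene is the set of true molecule positions per channel inside a
#' rectangular field of view. Four co-distribution modes cover the cases the
#' correlation analysis must distinguish: fully random channels; clustering
#' in one channel only; both channels clustered but on independent disc
#' sets (self-clustered yet randomly co-distributed, which must give a flat
#' cross-correlation); and co-clustering on shared disc centers.
#'
#' @param mode one of `"random"`, `"clustered_one_channel"`,
#'   `"clustered_both_independent"`, `"co_clustered"`.
#' @param fov_nm length-2 numeric, field of view width and height in nm.
#' @param density_um2 molecule density per um^2 for random channels
#'   (molecule counts are Poisson draws).
#' @param n_discs number of cluster discs per clustered channel.
#' @param disc_radius_nm cluster disc radius (nm).
#' @param mols_per_disc molecules placed uniformly inside each disc.
#' @param channels channel labels (length 2).
#' @param hole optional probe-free region, list(`center_nm`, `radius_nm`):
#'   molecules falling inside are suppressed (membrane detached from the
#'   coverslip; see [generate_topology_mask()]).
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(mode = c("random", "clustered_one_channel",
                                "clustered_both_independent", "co_clustered"),
                       fov_nm = c(10000, 10000), density_um2 = 10,
                       n_discs = 20, disc_radius_nm = 50, mols_per_disc = 10,
                       channels = c("ch1", "ch2"), hole = NULL) {
  mode <- match.arg(mode)
  if (any(fov_nm <= 0)) stop("field of view must have positive area")
  structure(list(mode = mode, fov_nm = fov_nm, density_um2 = density_um2,
                 n_discs = n_discs, disc_radius_nm = disc_radius_nm,
                 mols_per_disc = mols_per_disc, channels = channels,
                 hole = hole),
            class = "scene_spec")
}

place_discs_ <- function(n, radius, fov, max_attempts = 1e5) {
  cx <- numeric(0); cy <- numeric(0)
  attempts <- 0
  while (length(cx) < n) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("disc packing infeasible: could not place ", n,
           " non-overlapping discs of radius ", radius, " nm after ",
           max_attempts, " attempts")
    x <- stats::runif(1, radius, fov[1] - radius)
    y <- stats::runif(1, radius, fov[2] - radius)
    if (length(cx) == 0 || all((cx - x)^2 + (cy - y)^2 > (2 * radius)^2)) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
  }
  cbind(cx, cy)
}

fill_discs_ <- function(centers, radius, mols_per_disc) {
  n <- nrow(centers) * mols_per_disc
  disc <- rep(seq_len(nrow(centers)), each = mols_per_disc)
  # uniform in disc: r = R*sqrt(u)
  rr <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = centers[disc, 1] + rr * cos(th),
        y = centers[disc, 2] + rr * sin(th), disc = disc)
}

#' Generate a ground-truth scene from a specification
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed; identical seed and spec reproduce the scene
#'   bit-for-bit.
#' @return a `synthetic_scene`: list with `molecules` (per channel, a
#'   data.frame `x_nm`, `y_nm`, `disc` where `disc` is 0 for non-clustered
#'   molecules), the `spec` and the `seed`.
#' @export
generate_scene <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(seed)) set.seed(seed)
  fov <- spec$fov_nm
  area_um2 <- prod(fov) / 1e6
  rand_channel <- function() {
    n <- stats::rpois(1, spec$density_um2 * area_um2)
    data.frame(x_nm = stats::runif(n, 0, fov[1]),
               y_nm = stats::runif(n, 0, fov[2]), disc = 0L)
  }
  clus_channel <- function(centers) {
    m <- fill_discs_(centers, spec$disc_radius_nm, spec$mols_per_disc)
    data.frame(x_nm = m[, "x"], y_nm = m[, "y"], disc = as.integer(m[, "disc"]))
  }
  mols <- switch(spec$mode,
    random = list(rand_channel(), rand_channel()),
    clustered_one_channel = list(
      clus_channel(place_discs_(spec$n_discs, spec$disc_radius_nm, fov)),
      rand_channel()),
    clustered_both_independent = list(
      clus_channel(place_discs_(spec$n_discs, spec$disc_radius_nm, fov)),
      clus_channel(place_discs_(spec$n_discs, spec$disc_radius_nm, fov))),
    co_clustered = {
      centers <- place_discs_(spec$n_discs, spec$disc_radius_nm, fov)
      list(clus_channel(centers), clus_channel(centers))
    })
  names(mols) <- spec$channels
  if (!is.null(spec$hole)) {
    h <- spec$hole
    mols <- lapply(mols, function(df) {
      keep <- (df$x_nm - h$center_nm[1])^2 + (df$y_nm - h$center_nm[2])^2 >
        h$radius_nm^2
      df[keep, , drop = FALSE]
    })
  }
  structure(list(molecules = mols, spec = spec, seed = seed),
            class = "synthetic_scene")
}

#' Blink/observation model for sampling localizations from a scene
#'
#' Describes how often each molecule is observed over the acquisition and
#' with what precision. The default observation process draws a Poisson
#' number of activation bursts per molecule with uniformly random start
#' frames; each burst lasts a geometric number of consecutive frames with
#' mean `burst_len`. `burst_len = 1` gives memoryless single-frame
#' observations. Each observation is displaced from the true molecule
#' position by isotropic Gaussian noise with sd `sigma_nm`.
#'
#' @param mean_obs target mean observations per molecule (typical SMLM
#'   range 10-50).
#' @param n_frames number of acquisition frames (typical 5000-10000).
#' @param sigma_nm localization precision sd in nm (default 30); 0 places
#'   localizations exactly at molecule positions.
#' @param burst_len mean consecutive-frame burst length (>= 1).
#' @param fixed_obs if TRUE, every molecule is observed exactly
#'   `mean_obs` times (integer), bursts disabled.
#' @return a `blink_model` list.
#' @export
blink_model <- function(mean_obs = 20, n_frames = 5000, sigma_nm = 30,
                        burst_len = 3, fixed_obs = FALSE) {
  if (sigma_nm < 0) stop("sigma_nm must be >= 0")
  if (mean_obs <= 0 || n_frames < 1 || burst_len < 1)
    stop("invalid blink model")
  structure(list(mean_obs = mean_obs, n_frames = as.integer(n_frames),
                 sigma_nm = sigma_nm, burst_len = burst_len,
                 fixed_obs = fixed_obs),
            class = "blink_model")
}

#' Sample a localization table from a scene under a blink model
#'
#' @param scene a [synthetic_scene][generate_scene()].
#' @param blink a [blink_model()].
#' @param seed optional integer seed.
#' @return a [loc_table()] with a ground-truth `molecule_id` column
#'   (molecule ids are unique across channels).
#' @export
sample_localizations <- function(scene, blink = blink_model(), seed = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(blink, "blink_model"))
  if (!is.null(seed)) set.seed(seed)
  tabs <- lapply(names(scene$molecules), function(ch) {
    mols <- scene$molecules[[ch]]
    nm <- nrow(mols)
    empty <- function() loc_table(numeric(0), numeric(0), channel = ch,
                                  sigma_nm = numeric(0),
                                  molecule_id = integer(0))
    if (nm == 0) return(empty())
    if (blink$fixed_obs) {
      nobs <- rep(as.integer(round(blink$mean_obs)), nm)
      frames <- lapply(nobs, function(k)
        sample.int(blink$n_frames, k, replace = TRUE) - 1L)
    } else {
      nburst <- stats::rpois(nm, blink$mean_obs / blink$burst_len)
      frames <- lapply(nburst, function(k) {
        if (k == 0) return(integer(0))
        starts <- sample.int(blink$n_frames, k, replace = TRUE) - 1L
        lens <- 1L + stats::rgeom(k, 1 / blink$burst_len)
        unlist(lapply(seq_len(k), function(i) {
          f <- starts[i]:(starts[i] + lens[i] - 1L)
          f[f < blink$n_frames]
        }))
      })
      nobs <- lengths(frames)
    }
    tot <- sum(nobs)
    if (tot == 0) return(empty())
    mid <- rep(seq_len(nm), nobs)
    x <- mols$x_nm[mid] + stats::rnorm(tot, 0, blink$sigma_nm)
    y <- mols$y_nm[mid] + stats::rnorm(tot, 0, blink$sigma_nm)
    loc_table(x, y, unlist(frames), channel = ch,
              sigma_nm = blink$sigma_nm,
              molecule_id = mid)
  })
  # offset molecule ids so they are unique across channels
  sizes <- vapply(scene$molecules, nrow, integer(1))
  off <- cumsum(c(0L, sizes[-length(sizes)]))
  for (i in seq_along(tabs)) {
    if (nrow(tabs[[i]]) > 0) tabs[[i]]$molecule_id <- tabs[[i]]$molecule_id + off[i]
  }
  out <- do.call(rbind, tabs)
  out <- loc_table(out$x_nm, out$y_nm, out$frame, out$channel,
                   sigma_nm = out$sigma_nm, molecule_id = out$molecule_id)
  out
}

#' Simulate a live-cell frame-resolved localization stream
#'
#' Molecules perform 2D Brownian motion on a torus over the field of view
#' and are localized every frame with Gaussian precision `sigma_nm`. An
#' optional bound sub-population stays confined near supplied reference
#' points and diffuses with a reduced coefficient, emulating probes
#' transiently bound to clustered receptors.
#'
#' @param n_molecules free molecules.
#' @param fov_nm field of view (nm).
#' @param d_um2_s diffusion coefficient (um^2/s); must be >= 0.
#' @param dt_s frame interval (s), default 0.02.
#' @param n_frames frames to simulate.
#' @param sigma_nm localization precision (nm).
#' @param p_on per-frame probability a molecule is localized (default 1).
#' @param bound optional list: `ref_nm` (matrix of reference points),
#'   `n` (bound molecules), `d_um2_s` (their diffusion coefficient),
#'   `confine_nm` (confinement radius around the reference, default 80).
#' @param channel channel label.
#' @param seed optional seed.
#' @return a [loc_table()] with `molecule_id`; bound molecules carry ids
#'   greater than `n_molecules`.
#' @export
generate_live_stream <- function(n_molecules, fov_nm = c(10000, 10000),
                                 d_um2_s = 0.5, dt_s = 0.02, n_frames = 200,
                                 sigma_nm = 30, p_on = 1, bound = NULL,
                                 channel = "probe", seed = NULL) {
  if (d_um2_s < 0) stop("diffusion coefficient must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  step_sd <- sqrt(2 * d_um2_s * 1e6 * dt_s)  # nm per axis
  x <- stats::runif(n_molecules, 0, fov_nm[1])
  y <- stats::runif(n_molecules, 0, fov_nm[2])
  nb <- if (is.null(bound)) 0L else bound$n
  if (nb > 0) {
    ref <- bound$ref_nm
    ridx <- sample.int(nrow(ref), nb, replace = TRUE)
    bx <- ref[ridx, 1]; by <- ref[ridx, 2]
    bsd <- sqrt(2 * bound$d_um2_s * 1e6 * dt_s)
    conf <- if (is.null(bound$confine_nm)) 80 else bound$confine_nm
  }
  out_x <- vector("list", n_frames); out_y <- out_x; out_id <- out_x
  for (f in seq_len(n_frames)) {
    if (f > 1) {
      x <- (x + stats::rnorm(n_molecules, 0, step_sd)) %% fov_nm[1]
      y <- (y + stats::rnorm(n_molecules, 0, step_sd)) %% fov_nm[2]
      if (nb > 0) {
        nxp <- bx + stats::rnorm(nb, 0, bsd)
        nyp <- by + stats::rnorm(nb, 0, bsd)
        # reject steps that leave the confinement zone
        off <- (nxp - ref[ridx, 1])^2 + (nyp - ref[ridx, 2])^2 > conf^2
        nxp[off] <- bx[off]; nyp[off] <- by[off]
        bx <- nxp; by <- nyp
      }
    }
    ax <- x; ay <- y; aid <- seq_len(n_molecules)
    if (nb > 0) {
      ax <- c(ax, bx); ay <- c(ay, by)
      aid <- c(aid, n_molecules + seq_len(nb))
    }
    on <- if (p_on >= 1) rep(TRUE, length(ax)) else
      stats::runif(length(ax)) < p_on
    out_x[[f]] <- ax[on] + stats::rnorm(sum(on), 0, sigma_nm)
    out_y[[f]] <- ay[on] + stats::rnorm(sum(on), 0, sigma_nm)
    out_id[[f]] <- aid[on]
  }
  loc_table(unlist(out_x), unlist(out_y),
            frame = rep(seq_len(n_frames) - 1L, vapply(out_x, length, 1L)),
            channel = channel, sigma_nm = sigma_nm,
            molecule_id = unlist(out_id))
}
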