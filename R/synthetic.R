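#' Synthetic membrane-embedded four-helix-bundle generator
#'
#' Generates models and trajectories of a two-hairpin transmembrane bundle
#' with a planted contact architecture, so every analysis stage can be
#' validated against known truth without external data. Helices are rigid
#' ideal alpha-helices (rise 1.5 A/residue, 100 degrees/residue twist, radius
#' 2.3 A) placed as antiparallel rigid bodies; all conformational change is
#' inter-helix. Dynamics are an Ornstein-Uhlenbeck fluctuation of each helix
#' around its architecture's target placement, Markov-jump switching between
#' architectures, and optional irreversible membrane ejection of one hairpin
#' along +z.
#'
#' @name synthetic_data
NULL

#' Specification of a synthetic bundle/trajectory
#'
#' @param architecture one of `"TM2-TM3"`, `"TM1-TM4"`, `"TM1-TM3"`,
#'   `"mixed_B"` (TM2 touching both TM3 and TM4), `"separated"`; or a vector
#'   of such states for a switching trajectory (first = initial state).
#' @param contact_spacing axis-to-axis spacing of a planted contact pair (A).
#' @param noncontact_spacing spacing of the separated hairpins (A).
#' @param hairpin_spacing intra-hairpin helix spacing (A).
#' @param sigma fluctuation amplitude of each helix position (A, OU
#'   stationary standard deviation per axis).
#' @param tau OU relaxation time (frames).
#' @param switch_rate per-frame probability of jumping to another
#'   architecture.
#' @param ejection `NULL`, or `list(hairpin = "HP1"|"HP2", onset = frame,
#'   speed = A/frame)`.
#' @param n_frames,dt trajectory length and frame spacing.
#' @param seed RNG seed (all randomness derives from it).
#' @param representation `"CG"` (one BB bead per residue) or `"AA"` (adds N,
#'   C, O backbone atoms at ideal geometry).
#' @param slab_half_width half-width of the membrane slab (A); phosphate
#'   planes sit at +/- this z.
#' @return list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(architecture = "TM2-TM3",
                           contact_spacing = 8, noncontact_spacing = 18,
                           hairpin_spacing = 10,
                           sigma = 1, tau = 20, switch_rate = 0,
                           ejection = NULL,
                           n_frames = 1000L, dt = 1, seed = 1L,
                           representation = c("CG", "AA"),
                           slab_half_width = 20) {
  representation <- match.arg(representation)
  known <- c("TM2-TM3", "TM1-TM4", "TM1-TM3", "mixed_B", "separated")
  bad <- setdiff(architecture, known)
  if (length(bad) > 0L)
    stopf("unknown architecture(s): %s", paste(bad, collapse = ", "))
  if (contact_spacing <= 0 || noncontact_spacing <= 0 || hairpin_spacing <= 0)
    stopf("spacings must be > 0")
  if (contact_spacing >= noncontact_spacing)
    stopf("inconsistent spacing set: contact spacing (%g) must be below the non-contact spacing (%g)",
          contact_spacing, noncontact_spacing)
  if (contact_spacing <= hairpin_spacing / 2)
    stopf("inconsistent spacing set: contact spacing (%g) cannot close the mixed geometry with hairpin spacing %g",
          contact_spacing, hairpin_spacing)
  if (sigma < 0) stopf("sigma must be >= 0")
  if (!is.null(ejection)) {
    if (!ejection$hairpin %in% c("HP1", "HP2")) stopf("ejection hairpin must be HP1 or HP2")
    if (ejection$onset >= n_frames) stopf("ejection onset must be < n_frames")
    if (is.null(ejection$speed)) ejection$speed <- 1
  }
  structure(list(architecture = architecture,
                 contact_spacing = contact_spacing,
                 noncontact_spacing = noncontact_spacing,
                 hairpin_spacing = hairpin_spacing,
                 sigma = sigma, tau = tau, switch_rate = switch_rate,
                 ejection = ejection, n_frames = as.integer(n_frames),
                 dt = dt, seed = as.integer(seed),
                 representation = representation,
                 slab_half_width = slab_half_width),
            class = "SyntheticSpec")
}

#' Ideal alpha-helix C-alpha trace
#'
#' Standard alpha-helix geometry: 1.5 A rise and 100 degrees twist per
#' residue on a 2.3 A radius, giving consecutive C-alpha distances of about
#' 3.8 A. The helix is centred on the origin and oriented along `axis`.
#'
#' @param n_res number of residues (`>= 4`).
#' @param axis helix axis direction (3-vector, any non-zero length).
#' @param phase initial twist angle (radians).
#' @param rise,twist,radius geometry overrides (A, radians, A).
#' @return `n_res x 3` coordinate matrix.
#' @export
build_ideal_helix <- function(n_res, axis = c(0, 0, 1), phase = 0,
                              rise = 1.5, twist = 100 * pi / 180, radius = 2.3) {
  if (n_res < 4L) stopf("need at least 4 residues for a helix, got %d", n_res)
  i <- seq_len(n_res) - 1L
  local <- cbind(radius * cos(phase + i * twist),
                 radius * sin(phase + i * twist),
                 i * rise - (n_res - 1L) * rise / 2)
  local %*% t(rotation_to_axis(axis))
}

# Proper rotation mapping e_z onto unit(axis).
rotation_to_axis <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  ez <- c(0, 0, 1)
  v <- c(ez[2] * a[3] - ez[3] * a[2],
         ez[3] * a[1] - ez[1] * a[3],
         ez[1] * a[2] - ez[2] * a[1])
  cth <- sum(ez * a)
  if (sum(v^2) < 1e-14) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 degree flip about x
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

# xy target placement of the four helix axes for one architecture.
# Row layouts keep the planted contact pair at `c` and everything else at
# >= hairpin + contact spacing; mixed_B closes TM2 onto both TM3 and TM4.
architecture_targets <- function(arch, c_sp, n_sp, h_sp) {
  pos <- switch(arch,
    "TM2-TM3" = list(TM1 = c(0, 0), TM2 = c(h_sp, 0),
                     TM3 = c(h_sp + c_sp, 0), TM4 = c(2 * h_sp + c_sp, 0)),
    "TM1-TM4" = list(TM2 = c(0, 0), TM1 = c(h_sp, 0),
                     TM4 = c(h_sp + c_sp, 0), TM3 = c(2 * h_sp + c_sp, 0)),
    "TM1-TM3" = list(TM2 = c(0, 0), TM1 = c(h_sp, 0),
                     TM3 = c(h_sp + c_sp, 0), TM4 = c(2 * h_sp + c_sp, 0)),
    "mixed_B" = {
      x3 <- sqrt(c_sp^2 - (h_sp / 2)^2)
      list(TM1 = c(-h_sp, 0), TM2 = c(0, 0),
           TM3 = c(x3, h_sp / 2), TM4 = c(x3, -h_sp / 2))
    },
    "separated" = list(TM1 = c(0, 0), TM2 = c(h_sp, 0),
                       TM3 = c(h_sp + n_sp, 0), TM4 = c(2 * h_sp + n_sp, 0)),
    stopf("unknown architecture '%s'", arch))
  pos[c("TM1", "TM2", "TM3", "TM4")]
}

# Internal (origin-centred) helix templates for the default subdomain map.
bundle_templates <- function(submap) {
  tms <- c("TM1", "TM2", "TM3", "TM4")
  dirs <- c(1, -1, 1, -1)   # antiparallel within each hairpin
  lapply(seq_along(tms), function(i) {
    iv <- submap$intervals[[tms[i]]]
    n <- iv[2L] - iv[1L]
    list(name = tms[i], residues = interval_residues(iv),
         xyz = build_ideal_helix(n, axis = c(0, 0, dirs[i]),
                                 phase = (i - 1) * pi / 2))
  })
}

place_bundle <- function(templates, offsets) {
  do.call(rbind, lapply(templates, function(tpl) {
    off <- offsets[[tpl$name]]
    sweep(tpl$xyz, 2L, c(off[1L], off[2L], if (length(off) > 2L) off[3L] else 0),
          "+")
  }))
}

#' Build a synthetic bundle model with a planted architecture
#'
#' Four antiparallel TM helices at the architecture's target spacings, with
#' an optional per-helix Gaussian placement jitter of `sigma` (A, applied as
#' a rigid xy offset per helix). Residues are numbered with the default
#' subdomain map; only TM-helix residues are emitted (connecting loops carry
#' no information for any downstream analysis here).
#'
#' @param spec a [synthetic_spec()].
#' @param submap subdomain map (default [default_tm_boundaries()]).
#' @return list: `$model` ([structure_model()]), `$submap`, `$slab`
#'   ([slab_series()] of length 1).
#' @export
build_bundle <- function(spec, submap = make_subdomain_map()) {
  templates <- bundle_templates(submap)
  targets <- architecture_targets(spec$architecture[1L], spec$contact_spacing,
                                  spec$noncontact_spacing, spec$hairpin_spacing)
  offsets <- with_seed(spec$seed, lapply(targets, function(t)
    t + stats::rnorm(2L, 0, spec$sigma)))
  xyz <- place_bundle(templates, offsets)
  resno <- unlist(lapply(templates, function(t) t$residues))
  atoms <- data.frame(chain = "A", resno = resno, resname = "ALA",
                      atom = if (spec$representation == "CG") "BB" else "CA",
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
  list(model = structure_model(atoms,
                               model_id = sprintf("synthetic_%s_seed%d",
                                                  spec$architecture[1L], spec$seed),
                               predictor = "synthetic"),
       submap = submap,
       slab = slab_series(spec$slab_half_width, -spec$slab_half_width, 1L))
}

#' Simulate a synthetic bundle trajectory
#'
#' Per-helix xy positions relax toward the current architecture's targets as
#' an Ornstein-Uhlenbeck process (relaxation time `tau`, stationary sd
#' `sigma` per axis); the architecture switches as a Markov jump process at
#' `switch_rate` per frame (uniform over the other states of
#' `spec$architecture`); an optional ejection translates one hairpin along +z
#' at constant speed from its onset, irreversibly. The full planted truth is
#' returned for assertions.
#'
#' @param spec a [synthetic_spec()].
#' @param submap subdomain map.
#' @return list: `$traj` ([trajectory()]), `$slab` ([slab_series()]),
#'   `$truth` (list: `state` per frame, `ejection`).
#' @export
simulate_trajectory <- function(spec, submap = make_subdomain_map()) {
  templates <- bundle_templates(submap)
  states <- spec$architecture
  tm <- c("TM1", "TM2", "TM3", "TM4")
  target_sets <- lapply(states, architecture_targets,
                        c_sp = spec$contact_spacing,
                        n_sp = spec$noncontact_spacing,
                        h_sp = spec$hairpin_spacing)
  nf <- spec$n_frames
  n_bead <- sum(vapply(templates, function(t) length(t$residues), integer(1L)))
  coords <- array(NA_real_, c(nf, n_bead, 3L))
  state_idx <- integer(nf)
  a <- exp(-1 / spec$tau)
  noise_sd <- spec$sigma * sqrt(1 - a^2)
  ej <- spec$ejection
  hp_res <- list(HP1 = interval_residues(submap$HP1),
                 HP2 = interval_residues(submap$HP2))
  resno <- unlist(lapply(templates, function(t) t$residues))
  with_seed(spec$seed, {
    s <- 1L
    pos <- lapply(target_sets[[s]], function(t)
      t + stats::rnorm(2L, 0, spec$sigma))
    zlift <- 0
    for (f in seq_len(nf)) {
      if (length(states) > 1L && spec$switch_rate > 0 &&
          stats::runif(1L) < spec$switch_rate) {
        others <- setdiff(seq_along(states), s)
        s <- others[sample.int(length(others), 1L)]
      }
      tgt <- target_sets[[s]]
      for (h in tm) {
        pos[[h]] <- tgt[[h]] + (pos[[h]] - tgt[[h]]) * a +
          stats::rnorm(2L, 0, noise_sd)
      }
      state_idx[f] <- s
      if (!is.null(ej) && f >= ej$onset) zlift <- zlift + ej$speed
      offs <- lapply(pos, function(p) c(p, 0))
      if (!is.null(ej) && zlift > 0) {
        lifted <- if (ej$hairpin == "HP1") c("TM1", "TM2") else c("TM3", "TM4")
        for (h in lifted) offs[[h]][3L] <- offs[[h]][3L] + zlift
      }
      coords[f, , ] <- place_bundle(templates, offs)
    }
  })
  particles <- data.frame(chain = "A", resno = resno, resname = "ALA",
                          atom = if (spec$representation == "CG") "BB" else "CA")
  list(traj = trajectory(particles, coords, dt = spec$dt,
                         representation = spec$representation),
       slab = slab_series(spec$slab_half_width, -spec$slab_half_width, nf),
       truth = list(state = states[state_idx],
                    state_index = state_idx,
                    ejection = ej))
}

#' Plant a per-region confidence (pLDDT) channel on a model
#'
#' Residues of `low_regions` get pLDDT drawn around `low`, everything else
#' around `high`, with additive Gaussian noise, clipped to `[0, 100]`.
#'
#' @param model a [structure_model()].
#' @param submap a [make_subdomain_map()].
#' @param low_regions character vector of region names (`"HP1"`, `"HP2"`, or
#'   any interval name of the submap); empty for a flat high profile.
#' @param high,low mean pLDDT of confident / doubtful regions.
#' @param noise_sd additive noise.
#' @param seed RNG seed.
#' @return The model with its `conf` channel set.
#' @export
emit_confidence <- function(model, submap, low_regions = character(),
                            high = 90, low = 45, noise_sd = 3, seed = 1L) {
  low_res <- integer()
  for (rg in low_regions) {
    iv <- if (rg == "HP1") submap$HP1 else if (rg == "HP2") submap$HP2
      else submap$intervals[[rg]]
    if (is.null(iv)) stopf("unknown region '%s'", rg)
    low_res <- c(low_res, interval_residues(iv))
  }
  a <- model$atoms
  base <- ifelse(a$resno %in% low_res, low, high)
  a$conf <- with_seed(seed,
    pmin(pmax(base + stats::rnorm(nrow(a), 0, noise_sd), 0), 100))
  structure_model(a, model_id = model$model_id, predictor = model$predictor)
}
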