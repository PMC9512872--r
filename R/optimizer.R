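#' Simplified empirical energy model for restrained pose optimization
#'
#' Four terms: quadratic clash repulsion beyond vdW contact, a Gaussian
#' hydrogen-bond well with an angular switch, a Gaussian hydrophobic-contact
#' well, and a flat-bottom quadratic restraint on core atoms that engages
#' only past `flat_bottom` displacement. The restraint threshold (0.5 A) and
#' the limited-step optimization contract are the load-bearing behaviors;
#' well depths and widths are package parameters, all exposed here.
#'
#' @param w_clash Clash weight (score units / A^2).
#' @param polar_shrink Reduction of the vdW contact distance for N/O--N/O
#'   pairs (A), so hydrogen-bonding heavy atoms may approach their ideal
#'   separation without clash penalty (the usual empirical-scoring
#'   treatment of polar contacts).
#' @param hbond List: `ideal` heavy-heavy distance (A), `width` (A),
#'   `weight`.
#' @param hydrophobic List: `ideal`, `width`, `weight`.
#' @param restraint List: `flat_bottom` (A), `k` (score units / A^2).
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(w_clash = 5, polar_shrink = 0.4,
                         hbond = list(ideal = 2.9, width = 0.4, weight = 2),
                         hydrophobic = list(ideal = 3.9, width = 0.6,
                                            weight = 0.2),
                         restraint = list(flat_bottom = 0.5, k = 10)) {
  stopifnot(hbond$width > 0, hydrophobic$width > 0,
            restraint$flat_bottom >= 0, polar_shrink >= 0)
  structure(list(w_clash = w_clash, polar_shrink = polar_shrink,
                 hbond = hbond, hydrophobic = hydrophobic,
                 restraint = restraint),
            class = "energy_model")
}

# angular switch: 1 at a linear D-H...A geometry, fading to 0 at the cutoff
# angle (120 deg) and below. cos(120 deg) = -0.5.
hbond_angular <- function(cos_theta) {
  pmin(1, pmax(0, (-cos_theta - 0.5) / 0.5))
}

#' Energy and analytic gradient of a pose in its site
#'
#' Only ligand atoms carry gradient; the receptor is rigid. The core
#' restraint is evaluated against `core_ref` (the input core coordinates); if
#' omitted, the pose's current core coordinates are used and the restraint
#' term is zero.
#'
#' @param p A [pose()].
#' @param site A [binding_site()].
#' @param model An [energy_model()].
#' @param core_ref Optional reference coordinate matrix for the core atoms.
#' @return List with `E` (scalar) and `grad` (ligand-atom x 3 matrix).
#' @export
pose_energy <- function(p, site, model = energy_model(), core_ref = NULL) {
  lig <- p$ligand
  rec <- site$receptor
  n <- n_atoms(lig)
  grad <- matrix(0, n, 3)
  E <- 0
  li <- heavy_idx(lig)
  ri <- heavy_idx(rec)

  # clash repulsion: quadratic in penetration beyond vdW contact; polar
  # (N/O) pairs get a shrunken contact so hbond partners can reach their
  # ideal separation unpenalized
  if (length(li) && length(ri)) {
    rec_polar <- rec$elements[ri] %in% c("N", "O")
    for (i in li) {
      dx <- sweep(rec$xyz[ri, , drop = FALSE], 2, lig$xyz[i, ], "-")
      d <- sqrt(rowSums(dx^2))
      contact <- lig$vdw[i] + rec$vdw[ri]
      if (lig$elements[i] %in% c("N", "O"))
        contact <- contact - model$polar_shrink * rec_polar
      pen <- contact - d
      hit <- which(pen > 0 & d > 1e-9)
      if (length(hit)) {
        E <- E + model$w_clash * sum(pen[hit]^2)
        # dE/dxi = -2 w pen * d(d)/dxi ; d(d)/dxi = (xi - xr)/d = -dx/d
        gi <- colSums((2 * model$w_clash * pen[hit] / d[hit]) *
                        dx[hit, , drop = FALSE])
        grad[i, ] <- grad[i, ] + gi
      }
    }
  }

  feats <- ligand_features(lig)
  rec_no <- which(rec$elements %in% c("N", "O"))
  rec_cs <- which(rec$elements %in% c("C", "S"))
  hb <- model$hbond

  gauss_term <- function(i, targets, w, ideal, width) {
    # distance-Gaussian attraction between ligand atom i and receptor atoms
    dx <- sweep(rec$xyz[targets, , drop = FALSE], 2, lig$xyz[i, ], "-")
    d <- sqrt(rowSums(dx^2))
    ok <- d > 1e-9
    G <- exp(-(d - ideal)^2 / (2 * width^2))
    E <<- E - w * sum(G[ok])
    # dE/dxi = -w G'(d) dd/dxi with dd/dxi = -dx/d
    coef <- -w * G[ok] * (d[ok] - ideal) / width^2 / d[ok]
    grad[i, ] <<- grad[i, ] + colSums(coef * dx[ok, , drop = FALSE])
  }

  # hydrogen-bond wells
  if (length(rec_no)) {
    for (i in feats$donors) {
      hs <- explicit_h(lig, i)
      if (!length(hs)) {
        gauss_term(i, rec_no, hb$weight, hb$ideal, hb$width)
        next
      }
      h <- hs[1]
      for (a in rec_no) {
        dvec <- rec$xyz[a, ] - lig$xyz[i, ]
        d <- sqrt(sum(dvec^2))
        if (d < 1e-9) next
        G <- exp(-(d - hb$ideal)^2 / (2 * hb$width^2))
        u <- lig$xyz[i, ] - lig$xyz[h, ]   # H -> D
        v <- rec$xyz[a, ] - lig$xyz[h, ]   # H -> A
        nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
        if (nu < 1e-9 || nv < 1e-9) next
        ct <- sum(u * v) / (nu * nv)
        A <- hbond_angular(ct)
        if (G < 1e-12 || (A == 0 && G < 1e-12)) next
        E <- E - hb$weight * G * A
        # distance part (moves D only; A is receptor)
        dGdd <- -G * (d - hb$ideal) / hb$width^2
        grad[i, ] <- grad[i, ] - hb$weight * A * dGdd * (-dvec / d)
        # angular part (moves D and H) on the open ramp
        if (A > 0 && A < 1) {
          dA_dct <- -2
          dct_du <- v / (nu * nv) - ct * u / nu^2
          dct_dv <- u / (nu * nv) - ct * v / nv^2
          gD <- dct_du                      # d(ct)/dD
          gH <- -dct_du - dct_dv            # d(ct)/dH
          grad[i, ] <- grad[i, ] - hb$weight * G * dA_dct * gD
          grad[h, ] <- grad[h, ] - hb$weight * G * dA_dct * gH
        }
      }
    }
    for (i in feats$acceptors)
      gauss_term(i, rec_no, hb$weight, hb$ideal, hb$width)
  }

  # hydrophobic wells: ligand C/S vs receptor C/S
  hp <- model$hydrophobic
  lig_cs <- intersect(li, which(lig$elements %in% c("C", "S")))
  if (length(rec_cs))
    for (i in lig_cs) gauss_term(i, rec_cs, hp$weight, hp$ideal, hp$width)

  # flat-bottom core restraint
  core_idx <- setdiff(seq_len(n), p$fragment_atom_indices)
  if (!is.null(core_ref) && length(core_idx)) {
    rs <- model$restraint
    dx <- lig$xyz[core_idx, , drop = FALSE] - core_ref
    disp <- sqrt(rowSums(dx^2))
    over <- which(disp > rs$flat_bottom)
    if (length(over)) {
      E <- E + rs$k * sum((disp[over] - rs$flat_bottom)^2)
      coef <- 2 * rs$k * (disp[over] - rs$flat_bottom) / disp[over]
      grad[core_idx[over], ] <- grad[core_idx[over], , drop = FALSE] +
        coef * dx[over, , drop = FALSE]
    }
  }

  list(E = E, grad = grad)
}

#' Restrained gradient optimization of a pose
#'
#' Steepest descent with a limited step length: per iteration no atom moves
#' more than `config$opt_max_step`; a step that raises the energy is halved
#' (up to `config$opt_max_halvings` times) so accepted energies are
#' non-increasing. Converges when the energy change drops below
#' `config$opt_tol` or after `config$opt_max_iter` iterations. Core atoms are
#' restrained to their input coordinates through the model's flat-bottom
#' term; receptor atoms never move.
#'
#' @param p A [pose()].
#' @param site A [binding_site()].
#' @param model An [energy_model()].
#' @param config A [growlite_config()].
#' @return List with `pose` (optimized), `E_start`, `E_end`, `iterations`,
#'   `converged`, and `error` (TRUE when the starting energy was non-finite
#'   and the pose is returned unmodified).
#' @export
optimize_pose <- function(p, site, model = energy_model(),
                          config = growlite_config()) {
  config <- as_config(config)
  core_idx <- setdiff(seq_len(n_atoms(p$ligand)), p$fragment_atom_indices)
  core_ref <- p$ligand$xyz[core_idx, , drop = FALSE]
  cur <- pose_energy(p, site, model, core_ref)
  if (!is.finite(cur$E)) {
    warning("non-finite starting energy; pose returned unmodified")
    return(list(pose = p, E_start = cur$E, E_end = cur$E, iterations = 0L,
                converged = FALSE, error = TRUE))
  }
  E_start <- cur$E
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(config$opt_max_iter)) {
    g <- cur$grad
    gmax <- max(sqrt(rowSums(g^2)))
    if (gmax < 1e-10) { converged <- TRUE; break }
    alpha <- min(1, config$opt_max_step / gmax)
    accepted <- FALSE
    for (h in 0:config$opt_max_halvings) {
      trial <- p
      step <- -alpha * g
      stopifnot(max(sqrt(rowSums(step^2))) <= config$opt_max_step + 1e-12)
      trial$ligand$xyz <- p$ligand$xyz + step
      nxt <- pose_energy(trial, site, model, core_ref)
      if (is.finite(nxt$E) && nxt$E <= cur$E) {
        accepted <- TRUE
        dE <- cur$E - nxt$E
        p <- trial; cur <- nxt; iters <- it
        if (dE < config$opt_tol) converged <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted || converged) { if (!accepted) converged <- TRUE; break }
  }
  list(pose = p, E_start = E_start, E_end = cur$E, iterations = iters,
       converged = converged, error = FALSE)
}
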