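# Validation machinery: cross-growing case construction, fragment RMSD,
# binomial success statistics, interaction maintenance, enrichment.

mol_graph_colored <- function(mol) {
  g <- mol_graph(mol, heavy_only = TRUE)
  el <- igraph::vertex_attr(g, "element")
  g <- igraph::set_vertex_attr(g, "color",
                               value = match(el, names(.vdw_table), nomatch = 99L))
  if (igraph::ecount(g))
    g <- igraph::set_edge_attr(g, "color",
                               value = as.integer(igraph::edge_attr(g, "order")))
  g
}

case_rejection <- function(reason, detail = "") {
  structure(list(reason = reason, detail = detail), class = "case_rejection")
}

#' @export
print.case_rejection <- function(x, ...) {
  cat("<case rejected:", x$reason,
      if (nzchar(x$detail)) paste0("(", x$detail, ")") else "", ">\n")
  invisible(x)
}

#' Build a cross-growing test case from two aligned complexes
#'
#' The two ligands must differ by exactly one connected substituent joined to
#' the common core by one acyclic single bond: every such bond of the larger
#' ligand is cut in turn and the core side compared (element- and bond-order
#' aware graph isomorphism) against the smaller ligand. On success the core
#' is posed from `complex_a`'s ligand (the growing structure), the fragment
#' and the full reference ligand come from `complex_b` and are held out of
#' all growing inputs.
#'
#' @param complex_a,complex_b Lists with `$site` (a [binding_site()]) and
#'   `$ligand` (a `growlite_mol`), pre-aligned in one frame. `complex_a` is
#'   the growing structure; `complex_b` supplies the held-out reference.
#' @param case_id Identifier.
#' @return A `cross_grow_case`, or a `case_rejection` with a coded `reason`
#'   (`"too_large"`, `"no_extra_substituent"`,
#'   `"no_single_bond_substituent"`).
#' @export
build_case <- function(complex_a, complex_b, case_id = "case") {
  A <- complex_a$ligand
  B <- complex_b$ligand
  hA <- heavy_idx(A); hB <- heavy_idx(B)
  if (length(hA) > 40 || length(hB) > 40)
    return(case_rejection("too_large", "exact search limited to 40 heavy atoms"))
  if (length(hB) <= length(hA))
    return(case_rejection("no_extra_substituent",
                          "target ligand is not larger than the growing ligand"))
  gA <- mol_graph_colored(A)
  Bh <- subset_mol(B, hB)               # heavy-atom molecule, B indexing via hB
  gB <- mol_graph_colored(B)
  rb <- ring_bonds(Bh)
  bonds <- Bh$bonds
  for (k in seq_len(nrow(bonds))) {
    if (bonds[k, 3] != 1 || rb[k]) next
    g2 <- igraph::delete_edges(
      gB, igraph::get_edge_ids(gB, bonds[k, 1:2]))
    comp <- igraph::components(g2)$membership
    for (side in 1:2) {
      u <- bonds[k, side]               # core-side attachment candidate
      v <- bonds[k, 3 - side]
      core_v <- which(comp == comp[u])
      if (length(core_v) != length(hA)) next
      sub <- igraph::induced_subgraph(gB, core_v)
      iso <- igraph::isomorphisms(sub, gA, method = "vf2")
      if (!length(iso)) next
      mapping <- as.integer(iso[[1]])   # sub vertex -> A heavy vertex
      a_attach_h <- mapping[match(u, core_v)]
      a_attach <- hA[a_attach_h]
      anchor <- mark_core(A, a_attach)
      frag_h <- hB[which(comp != comp[u])]
      frag_all <- sort(unique(c(frag_h, unlist(lapply(frag_h, function(i) {
        nb <- mol_neighbors(B, i); nb[B$elements[nb] == "H"]
      })))))
      fragment <- subset_mol(B, frag_all, name = paste0(case_id, "_frag"))
      return(structure(list(
        growing_site = complex_a$site,
        core = anchor,
        target_fragment = fragment,
        reference_ligand = B,
        case_id = case_id), class = "cross_grow_case"))
    }
  }
  case_rejection("no_single_bond_substituent",
                 "difference is not one substituent on one acyclic single bond")
}

#' @export
print.cross_grow_case <- function(x, ...) {
  cat(sprintf(
    "<cross-growing case '%s': core %d atoms, fragment %d atoms, site '%s'>\n",
    x$case_id, n_atoms(x$core$core), n_atoms(x$target_fragment),
    x$growing_site$frame_id))
  invisible(x)
}

#' Symmetry-corrected fragment RMSD
#'
#' Heavy-atom RMSD between a pose's fragment and the reference fragment,
#' minimized over all graph automorphism matchings (element- and bond-order
#' aware), with coordinates taken in place — no superposition, since both
#' structures live in one aligned frame.
#'
#' @param p A [pose()] (or a bare `growlite_mol` fragment).
#' @param reference The reference fragment as a `growlite_mol` sharing the
#'   fragment's heavy-atom graph.
#' @return RMSD in Angstrom.
#' @export
fragment_rmsd <- function(p, reference) {
  frag <- if (inherits(p, "growlite_pose")) pose_fragment(p) else p
  hf <- heavy_idx(frag); hr <- heavy_idx(reference)
  if (length(hf) != length(hr))
    stop("fragment and reference differ in heavy-atom count")
  gf <- mol_graph_colored(frag)
  gr <- mol_graph_colored(reference)
  iso <- igraph::isomorphisms(gf, gr, method = "vf2")
  if (!length(iso))
    stop("fragment and reference heavy-atom graphs do not match")
  xa <- frag$xyz[hf, , drop = FALSE]
  xb <- reference$xyz[hr, , drop = FALSE]
  best <- Inf
  for (m in iso) {
    m <- as.integer(m)
    r <- sqrt(mean(rowSums((xa - xb[m, , drop = FALSE])^2)))
    if (r < best) best <- r
  }
  best
}

#' Half-width of the normal-approximation 95% binomial confidence interval
#'
#' `1.96 * sqrt(rate * (1 - rate) / n)`, the binary-classifier interval used
#' for sub-2-Angstrom success rates.
#'
#' @param rate Success fraction in `[0, 1]`.
#' @param n Number of cases.
#' @return Half-width as a fraction.
#' @export
binomial_ci_half_width <- function(rate, n) {
  stopifnot(n >= 1, rate >= 0, rate <= 1)
  1.96 * sqrt(rate * (1 - rate) / n)
}

#' Success statistics for a set of fragment RMSDs
#'
#' A case succeeds when its fragment RMSD is below `threshold` (conventional
#' 2 A); the 95% interval uses the normal approximation to the binomial.
#'
#' @param rmsds Numeric vector of RMSDs (Angstrom).
#' @param threshold Success threshold.
#' @return Object of class `success_stats` with `n`, `successes`, `rate`,
#'   `ci_half_width`.
#' @export
success_stats <- function(rmsds, threshold = 2.0) {
  if (!length(rmsds)) stop("no RMSD values")
  n <- length(rmsds)
  s <- sum(rmsds < threshold)
  rate <- s / n
  structure(list(n = n, successes = s, rate = rate,
                 ci_half_width = binomial_ci_half_width(rate, n)),
            class = "success_stats")
}

#' @export
print.success_stats <- function(x, ...) {
  cat(sprintf("success rate %.1f +/- %.1f%% (95%% CI, n = %d)\n",
              100 * x$rate, 100 * x$ci_half_width, x$n))
  invisible(x)
}

#' Interaction maintenance of a grown pose
#'
#' Regenerates search points from the grown pose and checks, per type, which
#' input points are regenerated within 2 A by a same-type point (greedy
#' one-to-one matching).
#'
#' @param input_points Search points the growing was asked to maintain.
#' @param grown_pose A [pose()] or ligand `growlite_mol`.
#' @param site The [binding_site()].
#' @param config A [growlite_config()].
#' @return Data frame with one row per type present in `input_points`:
#'   `type`, `n`, `maintained`, `fraction`, `ci_half_width`.
#' @export
interaction_maintenance <- function(input_points, grown_pose, site,
                                    config = growlite_config()) {
  config <- as_config(config)
  lig <- if (inherits(grown_pose, "growlite_pose")) grown_pose$ligand
         else grown_pose
  regen <- detect_interactions(site, lig, config)
  m <- match_point_sets(input_points, regen, radius = 2.0)
  types <- vapply(input_points, function(p) p$type, character(1))
  out <- lapply(unique(types), function(tp) {
    idx <- which(types == tp)
    kept <- sum(m[, 1] %in% idx)
    frac <- kept / length(idx)
    data.frame(type = tp, n = length(idx), maintained = kept,
               fraction = frac,
               ci_half_width = binomial_ci_half_width(frac, length(idx)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# rank-statistic AUC with mid-ranks for ties
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  na <- sum(labels); nd <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - na * (na + 1) / 2) / (na * nd)
}

#' ROC/AUC enrichment with a stratified bootstrap confidence interval
#'
#' AUC by the rank statistic (mid-ranks for ties; higher scores rank actives
#' first). The 95% interval is the 2.5/97.5 percentile over `n_boot`
#' stratified resamples: actives and inactives are resampled separately, so
#' every resample keeps both classes.
#'
#' @param scores Numeric scores, higher = predicted active.
#' @param labels Logical (or 0/1) activity labels.
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed for the resampling.
#' @return Object of class `enrichment_result`: `auc`, `ci` (length 2),
#'   `roc` (data frame `fpr`, `tpr`), `n_active`, `n_decoy`.
#' @export
enrichment <- function(scores, labels, n_boot = 1000, seed = 7) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels))
    stop("enrichment needs at least one active and one inactive")
  auc <- auc_rank(scores, labels)
  ia <- which(labels); id <- which(!labels)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    sa <- ia[sample.int(length(ia), replace = TRUE)]
    sd_ <- id[sample.int(length(id), replace = TRUE)]
    idx <- c(sa, sd_)
    auc_rank(scores[idx], labels[idx])
  }, numeric(1))
  ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  # ROC: sweep the threshold over distinct scores, descending
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(cumsum(l), grp, max)
  fp <- tapply(cumsum(!l), grp, max)
  roc <- data.frame(fpr = c(0, fp / length(id)), tpr = c(0, tp / length(ia)))
  structure(list(auc = auc, ci = ci, roc = roc,
                 n_active = length(ia), n_decoy = length(id),
                 n_boot = n_boot),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% bootstrap CI %.3f-%.3f; %d actives, %d decoys)\n",
              x$auc, x$ci[1], x$ci[2], x$n_active, x$n_decoy))
  invisible(x)
}

#' @export
plot.enrichment_result <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Molecular-weight ranking baseline AUC
#'
#' Sorting by descending molecular weight (heavier = predicted more active),
#' the residual-discrimination baseline for property-matched libraries.
#'
#' @param library List of `growlite_mol`.
#' @param labels Logical activity labels.
#' @return AUC of the molecular-weight score.
#' @export
mw_baseline <- function(library, labels) {
  mw <- vapply(library, molecular_weight, numeric(1))
  auc_rank(mw, labels)
}

# rotatable bonds in the medicinal-chemistry sense: acyclic single bonds
# between heavy atoms that each have >= 2 heavy neighbors
count_rotatable <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(0L)
  rb <- ring_bonds(mol)
  hdeg <- vapply(seq_len(n_atoms(mol)), function(i) {
    nb <- mol_neighbors(mol, i); sum(mol$elements[nb] != "H")
  }, numeric(1))
  sum(b[, 3] == 1 & !rb &
        mol$elements[b[, 1]] != "H" & mol$elements[b[, 2]] != "H" &
        hdeg[b[, 1]] >= 2 & hdeg[b[, 2]] >= 2)
}

#' Rule-of-Three-style property record of a fragment
#'
#' Molecular weight, hydrogen-bond donor and acceptor counts, a crude
#' atom-count logP estimate, rotatable-bond count and a crude TPSA estimate.
#' The logP/TPSA heuristics are coarse by design: they exist to drive decoy
#' property matching, not to predict physical partitioning.
#'
#' @param mol A `growlite_mol`.
#' @return One-row data frame: `mw`, `hbd`, `hba`, `clogp`, `rotb`, `tpsa`.
#' @export
ro3_properties <- function(mol) {
  f <- ligand_features(mol)
  el <- mol$elements
  hv <- heavy_idx(mol)
  nH_on <- function(i) attached_hydrogens(mol, i)
  tpsa <- 0
  for (i in hv) {
    if (el[i] == "O") tpsa <- tpsa + if (nH_on(i) >= 1) 20.23 else 17.07
    if (el[i] == "N") tpsa <- tpsa + if (nH_on(i) >= 1) 26.02 else 12.89
  }
  clogp <- 0.36 * sum(el == "C") + 0.88 * sum(el == "S") -
    0.74 * sum(el == "N") - 0.52 * sum(el == "O") +
    0.35 * sum(el %in% c("F", "Cl", "Br", "I"))
  data.frame(mw = molecular_weight(mol),
             hbd = length(f$donors),
             hba = length(f$acceptors),
             clogp = clogp,
             rotb = count_rotatable(mol),
             tpsa = tpsa)
}

#' Greedy property matching of decoys to actives
#'
#' Properties are z-scored on the pool statistics; each active claims its
#' nearest unclaimed pool member (greedy, without replacement).
#'
#' @param active_props Data frame of [ro3_properties()] rows for the actives.
#' @param pool_props Data frame for the candidate pool.
#' @param per_active Pool members matched to each active.
#' @return Integer vector of selected pool row indices.
#' @export
match_decoys <- function(active_props, pool_props, per_active = 1L) {
  cols <- intersect(names(active_props), names(pool_props))
  a <- as.matrix(active_props[, cols])
  p <- as.matrix(pool_props[, cols])
  mu <- colMeans(p)
  sdv <- apply(p, 2, stats::sd)
  sdv[sdv < 1e-9] <- 1
  az <- sweep(sweep(a, 2, mu), 2, sdv, "/")
  pz <- sweep(sweep(p, 2, mu), 2, sdv, "/")
  used <- logical(nrow(p))
  picks <- integer()
  for (rep_k in seq_len(per_active)) {
    for (i in seq_len(nrow(a))) {
      d <- colSums((t(pz) - az[i, ])^2)
      d[used] <- Inf
      j <- which.min(d)
      used[j] <- TRUE
      picks <- c(picks, j)
    }
  }
  picks
}
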