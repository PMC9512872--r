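dummy_site <- function() binding_site(molecule("C", matrix(c(9, 9, 9), 1)))

test_that("build_case accepts a single-substituent pair and poses the core", {
  ca <- list(site = dummy_site(), ligand = mk_benzene())
  cb <- list(site = dummy_site(), ligand = mk_toluene())
  cs <- build_case(ca, cb, "tolbenz")
  expect_s3_class(cs, "cross_grow_case")
  expect_equal(sum(cs$target_fragment$elements != "H"), 1)   # methyl
  expect_equal(n_atoms(cs$core$core), 6)
  # core posed from the growing structure's ligand
  expect_lt(max(abs(cs$core$core$xyz - mk_benzene()$xyz)), 1e-9)
  expect_identical(cs$reference_ligand$name, "toluene")
})

test_that("build_case rejects ring fusions and multi-substituent differences", {
  ca <- list(site = dummy_site(), ligand = mk_benzene())
  naph <- molecule(rep("C", 10),
                   rbind(mk_benzene()$xyz, mk_benzene(2.405)$xyz[2:5, ]),
                   rbind(cbind(1:6, c(2:6, 1), 1L),
                         cbind(c(1, 7, 8, 9, 10), c(7, 8, 9, 10, 6), 1L)))
  rej <- build_case(ca, list(site = dummy_site(), ligand = naph), "naph")
  expect_s3_class(rej, "case_rejection")
  expect_equal(rej$reason, "no_single_bond_substituent")

  xylene <- molecule(rep("C", 8),
                     rbind(mk_benzene()$xyz, c(2.9, 0, 0), c(-2.9, 0, 0)),
                     rbind(mk_benzene()$bonds, c(1L, 7L, 1L), c(4L, 8L, 1L)))
  rej2 <- build_case(ca, list(site = dummy_site(), ligand = xylene), "xyl")
  expect_s3_class(rej2, "case_rejection")

  same <- build_case(ca, list(site = dummy_site(), ligand = mk_benzene()))
  expect_s3_class(same, "case_rejection")
  expect_equal(same$reason, "no_extra_substituent")
})

test_that("fragment RMSD is measured in place and symmetry-corrected", {
  fr <- build_chain_fragment("CCO")
  expect_equal(fragment_rmsd(fr, fr), 0)
  shifted <- fr
  shifted$xyz <- sweep(fr$xyz, 2, -c(2, 0, 0))
  expect_equal(fragment_rmsd(shifted, fr), 2.0, tolerance = 1e-9)

  # a 180-degree flip of a symmetric ring maps it onto itself: RMSD 0 under
  # automorphism matching even though atom indices moved
  ring <- mk_benzene()
  ring$bonds[, 3] <- 1L                     # saturated ring, full symmetry
  flipped <- ring
  flipped$xyz <- ring$xyz[c(4, 5, 6, 1, 2, 3), ]
  expect_equal(fragment_rmsd(flipped, ring), 0, tolerance = 1e-9)
  # Kekule alternation restricts the automorphisms: an odd-step rotation is
  # no longer a graph symmetry and the mismatch is detected
  bz <- mk_benzene()
  odd <- bz
  odd$xyz <- bz$xyz[c(2, 3, 4, 5, 6, 1), ]
  expect_gt(fragment_rmsd(odd, bz), 1)

  expect_error(fragment_rmsd(build_chain_fragment("CC"), fr), "heavy-atom")
})

test_that("fragment RMSD is invariant under joint rigid motion", {
  set.seed(77)
  fr <- build_chain_fragment("CC(C)O")
  other <- fr
  other$xyz <- fr$xyz + matrix(stats::rnorm(nrow(fr$xyz) * 3, sd = 0.3),
                               ncol = 3)
  r0 <- fragment_rmsd(other, fr)
  R <- rand_rot(); shift <- stats::rnorm(3)
  move <- function(m) { m$xyz <- sweep(m$xyz %*% t(R), 2, -shift); m }
  expect_equal(fragment_rmsd(move(other), move(fr)), r0, tolerance = 1e-9)
})

test_that("success statistics use the normal-approximation binomial interval", {
  expect_equal(binomial_ci_half_width(0.668, 425), 0.0448, tolerance = 1e-3)
  expect_equal(binomial_ci_half_width(0.770, 252), 0.0520, tolerance = 1e-3)
  st <- success_stats(c(0.4, 1.2, 3.1, 1.9, 2.0))   # 2.0 is not a success
  expect_equal(st$n, 5)
  expect_equal(st$successes, 3)
  expect_equal(st$rate, 0.6)
  st10 <- success_stats(rep(0.5, 10))
  expect_equal(st10$rate, 1)
  expect_equal(st10$ci_half_width, 0)
  expect_error(success_stats(numeric()), "no RMSD")
})

test_that("interaction maintenance scores per-type regeneration within 2 A", {
  cs <- plant_case(fixture_spec(seed = 51, planted_fragment = "CC"))
  site <- cs$growing_site
  ref <- cs$reference_ligand
  pts <- detect_interactions(site, ref)
  expect_gte(length(pts), 1)
  m_same <- interaction_maintenance(pts, ref, site)
  expect_true(all(m_same$fraction == 1))
  # displace the ligand 3 A: points regenerate (if at all) too far away
  moved <- ref
  moved$xyz <- sweep(ref$xyz, 2, -c(3, 3, 0) / sqrt(2))
  m_moved <- interaction_maintenance(pts, moved, site)
  expect_true(all(m_moved$fraction < 1))
})

test_that("rank AUC equals brute-force pair counting, including ties", {
  expect_equal(enrichment(c(5, 4, 3, 2, 1, 0), c(1, 1, 1, 0, 0, 0),
                          n_boot = 50)$auc, 1.0)
  expect_equal(enrichment(rep(1, 6), c(1, 1, 1, 0, 0, 0),
                          n_boot = 50)$auc, 0.5)
  expect_error(enrichment(1:3, c(1, 1, 1)), "at least one")
  set.seed(13)
  for (k in 1:10) {
    n <- sample(6:50, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(seq_len(8), n, replace = TRUE)   # plenty of ties
    expect_equal(enrichment(scores, labels, n_boot = 10)$auc,
                 brute_auc(scores, labels))
  }
})

test_that("bootstrap intervals narrow roughly as 1/sqrt(n)", {
  widths <- vapply(c(40, 160), function(n) {
    set.seed(99)
    scores <- c(stats::rnorm(n / 2, 1), stats::rnorm(n / 2, 0))
    labels <- rep(c(TRUE, FALSE), each = n / 2)
    e <- enrichment(scores, labels, n_boot = 400, seed = 5)
    diff(e$ci)
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("molecular-weight baseline reflects the weight-activity relation", {
  heavy <- build_chain_fragment("CCCCC")
  light <- build_chain_fragment("C")
  mid <- build_chain_fragment("CC")
  expect_equal(mw_baseline(list(mid, mid, mid, mid),
                           c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_gt(mw_baseline(list(heavy, heavy, light, mid),
                        c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_lt(mw_baseline(list(light, light, heavy, mid),
                        c(TRUE, TRUE, FALSE, FALSE)), 0.5)
})

test_that("Rule-of-Three properties count donors, acceptors and rotatables", {
  bz <- ro3_properties(mk_benzene())
  expect_equal(bz$hbd, 0)
  expect_equal(bz$hba, 0)
  expect_equal(bz$rotb, 0)
  expect_equal(bz$mw, 78.11, tolerance = 0.01)
  eth <- ro3_properties(build_chain_fragment("CCO"))   # ethanol
  expect_equal(eth$hbd, 1)
  expect_equal(eth$hba, 1)
})

test_that("greedy decoy matching keeps per-property means within one SD", {
  set.seed(8)
  actives <- lapply(c("CC", "CCC", "CCO", "CN", "CCN"), build_chain_fragment)
  pool <- lapply(1:60, function(i)
    build_chain_fragment(sample(c("CC", "CCC", "CCO", "CN", "CO", "CCN",
                                  "CCCC", "CCCO"), 1),
                         name = sprintf("p%02d", i)))
  ap <- do.call(rbind, lapply(actives, ro3_properties))
  pp <- do.call(rbind, lapply(pool, ro3_properties))
  picks <- match_decoys(ap, pp, per_active = 2L)
  sel <- pp[picks, ]
  for (col in names(ap)) {
    sd_pool <- stats::sd(pp[[col]])
    if (sd_pool < 1e-9) next
    expect_lt(abs(mean(sel[[col]]) - mean(ap[[col]])), sd_pool)
  }
})
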