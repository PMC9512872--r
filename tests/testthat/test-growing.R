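test_that("single-atom fragment yields exactly one pose", {
  core <- molecule(c("C", "C"), rbind(c(-1.54, 0, 0), c(0, 0, 0)),
                   matrix(c(1L, 2L, 1L), 1))
  anc <- core_anchor(core, 2, c(1, 0, 0))
  frag <- molecule("C", matrix(0, 1, 3), name = "methyl")
  poses <- enumerate_attachments(anc, frag)
  expect_length(poses, 1)
  # new bond length = sum of covalent radii, along the growth vector
  expect_equal(poses[[1]]$ligand$xyz[3, ], c(1.52, 0, 0), tolerance = 1e-9)
})

test_that("torsion sampling collapses 3-fold methyl symmetry to 4 unique poses", {
  bz <- mk_benzene()
  anc <- mark_core(bz, 1)
  poses <- enumerate_attachments(anc, mk_methane())
  # 12 torsion samples at 30 deg, 3-fold redundant under H permutation
  expect_length(poses, 4)
})

test_that("pose enumeration respects the max_poses cap", {
  core <- molecule(c("C", "C"), rbind(c(-1.54, 0, 0), c(0, 0, 0)),
                   matrix(c(1L, 2L, 1L), 1))
  anc <- core_anchor(core, 2, c(1, 0, 0))
  ethyl <- build_chain_fragment("CC", name = "ethyl")
  poses <- enumerate_attachments(anc, ethyl)
  expect_lte(length(poses), growlite_config()$max_poses)
  expect_gte(length(poses), 12)   # 12 new-bond torsions survive dedup
  cfg5 <- growlite_config(max_poses = 5L)
  expect_warning(p5 <- enumerate_attachments(anc, ethyl, cfg5), "truncated")
  expect_length(p5, 5)
})

test_that("close contacts match a brute-force double loop", {
  core <- molecule("C", matrix(c(-5, 0, 0), 1))
  anc <- core_anchor(core, 1, c(1, 0, 0))
  set.seed(33)
  for (rep_k in 1:5) {
    frag <- molecule(rep("C", 4), matrix(stats::rnorm(12, sd = 2), 4))
    rec <- molecule(rep("C", 6), matrix(stats::rnorm(18, sd = 3), 6))
    lig <- molecule(c(core$elements, frag$elements), rbind(core$xyz, frag$xyz))
    p <- pose(lig, 2:5)
    site <- binding_site(rec)
    brute <- 0L
    for (i in 1:4) for (j in 1:6) {
      d <- sqrt(sum((frag$xyz[i, ] - rec$xyz[j, ])^2))
      if (d >= 3.2 && d <= 4.0) brute <- brute + 1L
    }
    expect_identical(close_contacts(p, site), brute)
  }
  # far fragment: zero; single pair at 3.5: one
  far <- pose(molecule(c("C", "C"), rbind(c(-5, 0, 0), c(20, 0, 0))), 2L)
  expect_identical(close_contacts(far, binding_site(molecule("C", matrix(0, 1, 3)))), 0L)
  one <- pose(molecule(c("C", "C"), rbind(c(-5, 0, 0), c(3.5, 0, 0))), 2L)
  expect_identical(close_contacts(one, binding_site(molecule("C", matrix(0, 1, 3)))), 1L)
})

test_that("grow filters clashing fragments and reports them", {
  cs <- plant_case(fixture_spec(seed = 21))
  # a rigid rod too long for the cavity clashes in every orientation
  big <- mk_rigid_rod()
  expect_warning(hl <- grow(cs$core, cs$growing_site, list(big)),
                 "filtered")
  expect_length(hl, 0)
  expect_equal(hl$summary$n_filtered, 1)
  expect_error(grow(cs$core, cs$growing_site, list()), "empty")
})

test_that("an unsatisfiable search point empties the hit list", {
  cs <- plant_case(fixture_spec(seed = 22))
  sp <- list(search_point("donor", c(30, 0, 0), tolerance = 1))
  expect_warning(hl <- grow(cs$core, cs$growing_site,
                            list(cs$target_fragment), sp))
  expect_length(hl, 0)
})

test_that("the fitting fragment outranks and survives the oversized one", {
  cs <- plant_case(fixture_spec(seed = 23))
  fits <- cs$target_fragment
  toobig <- mk_rigid_rod()
  hl <- suppressWarnings(grow(cs$core, cs$growing_site, list(toobig, fits)))
  expect_gte(length(hl), 1)
  expect_equal(hl$poses[[1]]$fragment_id, fits$name)
})

test_that("core atoms never move during pose generation", {
  cs <- plant_case(fixture_spec(seed = 24))
  hl <- grow(cs$core, cs$growing_site, list(cs$target_fragment))
  core_xyz <- cs$core$core$xyz
  nc <- nrow(core_xyz)
  for (p in hl$poses)
    expect_identical(p$ligand$xyz[seq_len(nc), ], core_xyz)
})

test_that("growing is deterministic", {
  cs <- plant_case(fixture_spec(seed = 25))
  lib <- make_enrichment_set(seed = 25, n_actives = 3, n_decoys = 5)$library
  h1 <- suppressWarnings(grow(cs$core, cs$growing_site, lib))
  h2 <- suppressWarnings(grow(cs$core, cs$growing_site, lib))
  expect_identical(h1, h2)
})

test_that("adding search points never increases the surviving fragments", {
  cs <- plant_case(fixture_spec(seed = 26))
  lib <- make_enrichment_set(seed = 26, n_actives = 4, n_decoys = 8)$library
  h0 <- suppressWarnings(grow(cs$core, cs$growing_site, lib))
  surv0 <- vapply(h0$poses, function(p) p$fragment_id, character(1))
  # a satisfiable hydrophobic point near the lobe
  cen <- colMeans(cs$planted_pose$ligand$xyz[
    cs$planted_pose$fragment_atom_indices, , drop = FALSE])
  sp1 <- list(search_point("hydrophobic", cen, tolerance = 2.5))
  h1 <- suppressWarnings(grow(cs$core, cs$growing_site, lib, sp1))
  surv1 <- vapply(h1$poses, function(p) p$fragment_id, character(1))
  expect_true(all(surv1 %in% surv0))
  sp2 <- c(sp1, list(search_point("donor", cen, tolerance = 1.0)))
  h2 <- suppressWarnings(grow(cs$core, cs$growing_site, lib, sp2))
  surv2 <- vapply(h2$poses, function(p) p$fragment_id, character(1))
  expect_true(all(surv2 %in% surv1))
})

test_that("hit lists are ordered by combined score, ties by fragment id", {
  cs <- plant_case(fixture_spec(seed = 27))
  lib <- make_enrichment_set(seed = 27, n_actives = 4, n_decoys = 8)$library
  hl <- suppressWarnings(grow(cs$core, cs$growing_site, lib))
  df <- as.data.frame(hl)
  ord <- order(-df$combined, df$fragment_id, method = "radix")
  expect_identical(ord, seq_len(nrow(df)))
})

test_that("hit lists round-trip to SDF with score tags", {
  cs <- plant_case(fixture_spec(seed = 28))
  hl <- grow(cs$core, cs$growing_site, list(cs$target_fragment))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_hits(hl, path)
  back <- read_sdf(path)
  expect_length(back, length(hl))
  tg <- attr(back[[1]], "tags")
  expect_equal(as.numeric(tg[["combined_score"]]),
               hl$poses[[1]]$score$combined, tolerance = 1e-3)
  expect_equal(tg[["fragment_id"]], hl$poses[[1]]$fragment_id)
})
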