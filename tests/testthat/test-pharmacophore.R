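test_that("apolar ligands near a polar pocket generate no donor/acceptor points", {
  rec <- molecule(c("N", "O"), rbind(c(3, 0, 0), c(0, 3, 0)))
  site <- binding_site(rec)
  lig <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)),
                  matrix(c(1L, 2L, 1L), 1))
  pts <- detect_interactions(site, lig)
  expect_false(any(vapply(pts, function(p) p$type, character(1)) %in%
                     c("donor", "acceptor")))
})

test_that("a face-on hydrophobic ring generates one centroid point", {
  site <- binding_site(molecule("C", matrix(c(0, 0, 4), 1)))
  pts <- detect_interactions(site, mk_benzene())
  expect_length(pts, 1)
  expect_equal(pts[[1]]$type, "hydrophobic")
  expect_equal(pts[[1]]$position, c(0, 0, 0), tolerance = 1e-6)
})

test_that("an N-H at 3.0 A and 180 degrees to a receptor O is a donor point", {
  site <- binding_site(molecule("O", matrix(c(0, 0, 3.0), 1)))
  lig <- mk_nh_ligand()
  pts <- detect_interactions(site, lig)
  types <- vapply(pts, function(p) p$type, character(1))
  expect_equal(sum(types == "donor"), 1)
  expect_equal(pts[[which(types == "donor")]]$position, c(0, 0, 0),
               tolerance = 1e-6)
  # same geometry but bent below 120 degrees fails the angle test
  lig_bent <- lig
  lig_bent$xyz[2, ] <- c(1.01, 0, 0)      # H at 90 deg to the receptor O
  pts2 <- detect_interactions(site, lig_bent)
  expect_false(any(vapply(pts2, function(p) p$type, character(1)) == "donor"))
})

test_that("every emitted point coincides with a ligand atom, centroid or water", {
  cs <- plant_case(fixture_spec(seed = 31, planted_fragment = "CO"))
  site <- cs$growing_site
  lig <- cs$reference_ligand
  pts <- detect_interactions(site, lig)
  ring_cents <- NULL
  ok_pos <- rbind(lig$xyz, ring_cents)
  for (p in pts) {
    d <- sqrt(colSums((t(ok_pos) - p$position)^2))
    expect_lt(min(d), 1e-6)
  }
})

test_that("stable points require same type within 2 A, matched greedily", {
  a <- list(search_point("donor", c(0, 0, 0)))
  b19 <- search_point("donor", c(1.9, 0, 0))
  b21 <- search_point("donor", c(2.1, 0, 0))
  expect_length(stable_points(a, list(b19, b21)), 1)
  expect_length(stable_points(a, list(b21)), 0)
  expect_length(stable_points(a, list(search_point("acceptor", c(0, 0, 0)))), 0)
  ident <- list(search_point("donor", c(0, 0, 0)),
                search_point("hydrophobic", c(1, 1, 1)))
  expect_length(stable_points(ident, ident), 2)
})

test_that("stable-point matching is symmetric in cardinality", {
  set.seed(55)
  types <- c("donor", "acceptor", "hydrophobic")
  for (k in 1:10) {
    a <- lapply(seq_len(sample(3:8, 1)), function(i)
      search_point(sample(types, 1), stats::rnorm(3, sd = 2)))
    b <- lapply(seq_len(sample(3:8, 1)), function(i)
      search_point(sample(types, 1), stats::rnorm(3, sd = 2)))
    expect_equal(length(stable_points(a, b)), length(stable_points(b, a)))
  }
})

test_that("match_pose enforces every point within its tolerance", {
  lig <- mk_nh_ligand()                  # donor N at the origin
  p <- pose(lig, integer(0))
  expect_true(match_pose(p, list())$pass)
  expect_true(match_pose(p, list(search_point("donor", c(1.5, 0, 0),
                                              tolerance = 2)))$pass)
  expect_false(match_pose(p, list(search_point("donor", c(2.1, 0, 0),
                                               tolerance = 2)))$pass)
  # one ligand feature may satisfy several points
  two <- list(search_point("donor", c(0.5, 0, 0), tolerance = 2),
              search_point("donor", c(0, 0.5, 0), tolerance = 2))
  res <- match_pose(p, two)
  expect_true(res$pass)
  expect_equal(nrow(res$assignment), 2)
  expect_true(all(res$assignment$ok))
  # huge tolerance always passes; zero-ish tolerance needs coincidence
  expect_true(match_pose(p, list(search_point("donor", c(9, 9, 9),
                                              tolerance = 1e6)))$pass)
  expect_false(match_pose(p, list(search_point("donor", c(0, 0, 1e-3),
                                               tolerance = 1e-6)))$pass)
  expect_true(match_pose(p, list(search_point("donor", c(0, 0, 0),
                                              tolerance = 1e-6)))$pass)
})

test_that("vdW overlap formula reproduces the worked percentages", {
  expect_equal(vdw_overlap(0, 1.52, 1.70), 100)
  expect_equal(vdw_overlap(1.52 + 1.70, 1.52, 1.70), 0)
  expect_equal(vdw_overlap(1.20, 1.52, 1.70), (3.22 - 1.20) / 3.22 * 100,
               tolerance = 1e-9)
  # the alternative volume metric agrees at the extremes
  expect_equal(vdw_overlap(0, 1.52, 1.70, metric = "volume"), 100)
  expect_equal(vdw_overlap(3.4, 1.52, 1.70, metric = "volume"), 0)
})

test_that("water replacement emits confirmed typed points and flags waters", {
  # ligand C-C chain next to one water; a second water is far away
  lig <- build_chain_fragment("CC")
  lig$xyz <- sweep(lig$xyz, 2, -c(1, 0, 0))
  sp <- fixture_spec(seed = 4, pocket_kind = "spherical", pocket_radius = 5,
                     spacing = 1.2,
                     waters = rbind(c(1.0, 0.5, 0), c(0, -4, 0)))
  site <- make_pocket(sp)
  q <- water_replacement_query(site, lig)
  expect_equal(attr(q, "replaced"), 1L)       # only the near water
  expect_gte(length(q), 1)
  for (p in q) {
    expect_equal(p$source, "water")
    expect_equal(p$position, site$waters$xyz[1, ], tolerance = 1e-9)
  }
  # dummy hydrophobic interaction confirmed by the ligand's terminal carbons
  expect_true("hydrophobic" %in% vapply(q, function(p) p$type, character(1)))

  dry <- strip_waters(site)
  expect_warning(q2 <- water_replacement_query(dry, lig), "no waters")
  expect_length(q2, 0)
})

test_that("search points round-trip through JSON", {
  pts <- list(search_point("acceptor", c(1, 2, 3), 1.5),
              search_point("hydrophobic", c(-1, 0, 2)))
  path <- withr::local_tempfile(fileext = ".json")
  write_search_points(pts, path)
  back <- read_search_points(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$type, "acceptor")
  expect_equal(back[[1]]$position, c(1, 2, 3))
  expect_equal(back[[1]]$tolerance, 1.5)
  expect_equal(back[[2]]$tolerance, 2.0)
})
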