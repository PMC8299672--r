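toy_case <- function(seed = 1) {
  generate_synthetic_case(synthetic_case_config(seed = seed), scanner_pose = FALSE)
}

test_that("clone_jaw gives an isolated postop copy", {
  jaw <- toy_case()$maxilla
  cl <- clone_jaw(jaw)
  expect_equal(cl$stage, "postop")
  expect_identical(cl$mesh$vertices, jaw$mesh$vertices)
  expect_identical(lapply(cl$pivots, `[[`, "position"),
                   lapply(jaw$pivots, `[[`, "position"))
  moved <- move_jaw(cl, planned_move(translation = c(5, 0, 0)))
  expect_identical(jaw$stage, "preop")
  expect_identical(jaw$mesh$vertices, toy_case()$maxilla$mesh$vertices)
  cl2 <- clone_jaw(clone_jaw(jaw))
  expect_identical(cl2$mesh$vertices, jaw$mesh$vertices)
})

test_that("move_jaw translation shifts every pivot exactly", {
  jaw <- toy_case()$maxilla
  moved <- move_jaw(jaw, planned_move(translation = c(5, 0, 0)))
  for (nm in names(jaw$pivots)) {
    expect_equal(pivot_position(moved, nm) - pivot_position(jaw, nm), c(5, 0, 0))
  }
})

test_that("rotation about a pivot keeps it fixed and obeys the chord formula", {
  jaw <- toy_case()$maxilla
  rot <- planned_move(axis = c(1, 0, 0), angle_deg = 10, center = "Ie")
  moved <- move_jaw(jaw, rot)
  expect_equal(pivot_position(moved, "Ie"), pivot_position(jaw, "Ie"),
               tolerance = 1e-12)
  # chord length of any other pivot = 2 r sin(angle/2)
  for (nm in c("occ_left", "raphe_post")) {
    r <- sqrt(sum((pivot_position(jaw, nm) - pivot_position(jaw, "Ie"))^2))
    chord <- sqrt(sum((pivot_position(moved, nm) - pivot_position(jaw, nm))^2))
    # only the component perpendicular to the x axis rotates
    r_perp <- sqrt(sum(((pivot_position(jaw, nm) - pivot_position(jaw, "Ie"))[2:3])^2))
    expect_equal(chord, 2 * r_perp * sin(5 * pi / 180), tolerance = 1e-9)
  }
  expect_error(move_jaw(jaw, planned_move(axis = c(1, 0, 0), angle_deg = 5,
                                          center = "nope")),
               class = "unknown_pivot")
})

test_that("measure_displacements reports signed deltas post minus pre", {
  jaw <- toy_case()$maxilla
  expect_equal(max(measure_displacements(jaw, jaw)$euclidean), 0)
  moved <- move_jaw(clone_jaw(jaw), planned_move(translation = c(5, 0, 0)))
  rep <- measure_displacements(jaw, moved)
  expect_equal(rep$dx, rep(5, nrow(rep)))
  expect_equal(rep$dy, rep(0, nrow(rep)))
  expect_equal(rep$euclidean, rep(5, nrow(rep)))
  expect_equal(rep$pivot, sort(names(jaw$pivots)))
  expect_equal(rep$euclidean, sqrt(rep$dx^2 + rep$dy^2 + rep$dz^2), tolerance = 1e-12)
  other <- add_pivot(jaw, "extra", c(0, 0, 0))
  expect_error(measure_displacements(jaw, other), class = "pivot_mismatch")
})

test_that("a move and its inverse leave zero displacements", {
  jaw <- toy_case()$maxilla
  mv <- planned_move(translation = c(2, -1, 3), axis = c(0, 1, 0),
                     angle_deg = 7, center = "Ie")
  moved <- move_jaw(clone_jaw(jaw), mv)
  # inverse: undo translation, then rotate back about the (moved) center
  back <- move_jaw(moved, planned_move(translation = -mv$translation))
  back <- move_jaw(back, planned_move(axis = c(0, 1, 0), angle_deg = -7, center = "Ie"))
  rep <- measure_displacements(jaw, back)
  expect_lt(max(rep$euclidean), 1e-9)
})

test_that("a solver-constructed maxillary move reproduces target displacement magnitudes", {
  # asymmetric advancement 5 mm right / 3 mm left, midline 2 mm to the
  # left, posterior impaction 4 mm — solved as scalar constraints by an
  # independent least-squares oracle, then applied through move_jaw
  jaw <- toy_case()$maxilla
  pts <- lapply(jaw$pivots, `[[`, "position")
  constraints <- list(
    list(point = "occ_right", axis = 3L, target = 5),   # advance right molar (+z)
    list(point = "occ_left", axis = 3L, target = 3),    # advance left molar (+z)
    list(point = "Ie", axis = 1L, target = 2),          # midline 2 mm patient-left (+x)
    list(point = "raphe_post", axis = 2L, target = 4))  # posterior impaction (+y)
  sol <- solve_target_move(pts, constraints)
  expect_lt(sol$objective, 1e-8)
  ang <- sqrt(sum(sol$rotvec^2)) * 180 / pi
  mv <- planned_move(translation = sol$translation,
                     axis = if (ang > 0) sol$rotvec else NULL,
                     angle_deg = ang, center = c(0, 0, 0))
  moved <- move_jaw(clone_jaw(jaw), mv)
  rep <- measure_displacements(jaw, moved)
  get <- function(p, col) rep[rep$pivot == p, col]
  expect_equal(get("occ_right", "dz"), 5, tolerance = 0.05)
  expect_equal(get("occ_left", "dz"), 3, tolerance = 0.05)
  expect_equal(get("Ie", "dx"), 2, tolerance = 0.05)
  expect_equal(get("raphe_post", "dy"), 4, tolerance = 0.05)
})

test_that("open_rotation pivots about the hinge axis in the opening sense", {
  case <- toy_case()
  hinge <- pivot("hinge_axis", case$truth$hinge_canonical, "maxilla")
  mand <- case$mandible
  expect_identical(open_rotation(mand, hinge, 0)$mesh$vertices, mand$mesh$vertices)
  opened <- open_rotation(mand, hinge, 2)
  # hinge stays fixed; the lower incisor moves inferior and posterior
  hp <- transform_points(rotation_about_axis(c(1, 0, 0), 2, hinge$position),
                         hinge$position)
  expect_equal(hp, hinge$position, tolerance = 1e-12)
  d <- pivot_position(opened, "Ie") - pivot_position(mand, "Ie")
  expect_lt(d[2], 0)  # inferior
  expect_lt(d[3], 0)  # posterior
  r <- sqrt(sum((pivot_position(mand, "Ie") - hinge$position)[2:3]^2))
  expect_equal(sqrt(sum(d^2)), 2 * r * sin(1 * pi / 180), tolerance = 1e-9)
})

test_that("planning operations preserve rigidity and closed-mesh volume", {
  jaw <- toy_case()$maxilla
  v0 <- mesh_volume(jaw$mesh)
  mv <- planned_move(translation = c(4, -2, 6), axis = c(0.3, 0.5, 1),
                     angle_deg = 23, center = "Ie")
  moved <- move_jaw(clone_jaw(jaw), mv)
  expect_equal(mesh_volume(moved$mesh), v0, tolerance = 1e-6 * abs(v0))
  p0 <- pivot_matrix(jaw); p1 <- pivot_matrix(moved)
  expect_equal(pairwise_dists(p1), pairwise_dists(p0), tolerance = 1e-9)
})

test_that("export_splint_set writes the scenario-dependent STL sets", {
  case <- toy_case()
  hinge <- pivot("hinge_axis", case$truth$hinge_canonical, "maxilla")
  post_max <- move_jaw(clone_jaw(case$maxilla), planned_move(translation = c(0, 0, 4)))
  post_mand <- move_jaw(clone_jaw(case$mandible), planned_move(translation = c(0, 0, -2)))
  plan <- surgical_plan(case$maxilla, case$mandible, post_max, post_mand, hinge)

  d_bi <- withr::local_tempdir()
  bi <- export_splint_set(plan, "bimaxillary", d_bi)
  expect_equal(nrow(bi$members), 3L)
  expect_setequal(list.files(d_bi, pattern = "\\.stl$"), bi$members$file)
  expect_equal(bi$members$stage, c("postop", "preop", "postop"))
  expect_equal(bi$members$open_rotated, c(FALSE, FALSE, TRUE))

  d_lo <- withr::local_tempdir()
  lo <- export_splint_set(plan, "lower_only", d_lo)
  expect_equal(nrow(lo$members), 2L)
  expect_equal(lo$members$jaw, c("maxilla", "mandible"))
  expect_equal(lo$members$stage, c("preop", "postop"))

  d_up <- withr::local_tempdir()
  up <- export_splint_set(plan, "upper_only", d_up)
  expect_equal(nrow(up$members), 2L)
  expect_equal(up$members$stage, c("postop", "preop"))

  # re-import reproduces scene coordinates within STL float precision
  back <- read_stl(file.path(d_bi, "maxilla_postop.stl"))
  ord <- function(v) v[order(v[, 1], v[, 2], v[, 3]), ]
  expect_lt(max(abs(ord(back$vertices) - ord(post_max$mesh$vertices))), 1e-4)

  partial <- surgical_plan(case$maxilla, case$mandible, hinge_pivot = hinge)
  expect_error(export_splint_set(partial, "bimaxillary", withr::local_tempdir()),
               class = "missing_stage")
  no_hinge <- surgical_plan(case$maxilla, case$mandible, post_max, post_mand)
  expect_error(export_splint_set(no_hinge, "bimaxillary", withr::local_tempdir()),
               class = "missing_stage")
})

test_that("write_planning_sheet assembles the machine-readable protocol", {
  case <- toy_case()
  params <- hinge_axis_parameters(scale_landmarks(case$ceph_landmarks))
  d <- withr::local_tempdir()
  # mounting-only sheet
  write_planning_sheet(d, params)
  sheet <- jsonlite::read_json(file.path(d, "sheet.json"))
  expect_true(all(c("software", "frame", "mounting") %in% names(sheet)))
  expect_null(sheet$displacements)

  moved <- move_jaw(clone_jaw(case$maxilla), planned_move(translation = c(1, 2, 3)))
  rep <- measure_displacements(case$maxilla, moved)
  contacts <- detect_contacts(case$maxilla, case$mandible, 0.1)
  hinge <- pivot("hinge_axis", case$truth$hinge_canonical, "maxilla")
  plan <- surgical_plan(case$maxilla, case$mandible, moved,
                        clone_jaw(case$mandible), hinge)
  splints <- export_splint_set(plan, "bimaxillary", withr::local_tempdir())
  d2 <- withr::local_tempdir()
  photo <- occlusal_cant(case$frontal_landmarks)
  write_planning_sheet(d2, params, photo = photo,
                       displacements = list(maxilla = rep),
                       contacts = contacts, splints = splints)
  sheet2 <- jsonlite::read_json(file.path(d2, "sheet.json"))
  expect_true(all(c("mounting", "photo", "displacements", "contacts", "splints")
                  %in% names(sheet2)))
  # CSV round trip equals the in-memory report
  csv <- utils::read.csv(file.path(d2, "displacements.csv"))
  expect_equal(csv$pivot, rep$pivot)
  expect_equal(csv$dx, rep$dx, tolerance = 1e-8)
  expect_equal(csv$euclidean, rep$euclidean, tolerance = 1e-8)
})
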