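toy_map <- component_map(tibble::tibble(
  atom_label = c("N4", "P8", "C1", "C2"),
  component = c("choline", "phosphate", "glycerol", "tail")
))

test_that("component assignment is strict by default, permissive on demand", {
  atoms <- tibble::tibble(atom_label = c("N4", "P8", "C1", "C2"), z = 1:4)
  out <- assign_components(atoms, toy_map)
  expect_equal(out$bin, c("choline", "phosphate", "glycerol", "tail"))

  atoms2 <- tibble::tibble(atom_label = c("N4", "P8", "C1", "XX"), z = 1:4)
  expect_error(assign_components(atoms2, toy_map), "XX")
  perm <- assign_components(atoms2, toy_map, permissive = TRUE)
  expect_equal(sum(!is.na(perm$bin)), 3)
  expect_equal(attr(perm, "unmapped"), "XX")
})

test_that("component maps validate and read from YAML/JSON", {
  expect_error(component_map(tibble::tibble(
    atom_label = c("A", "A"), component = c("tail", "tail"))), "exactly one")
  expect_error(component_map(tibble::tibble(
    atom_label = c("A", "B"), component = c("tail", "tail"))), "two bins")

  yml <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("map:", "  N4: choline", "  P8: phosphate"), yml)
  m <- read_component_map(yml)
  expect_s3_class(m, "component_map")
  expect_equal(nrow(m), 2)

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(N4 = "choline", C2 = "tail"), js, auto_unbox = TRUE)
  m2 <- read_component_map(js)
  expect_equal(sort(m2$component), c("choline", "tail"))
})

test_that("generator pseudo-lipids carry the expected per-component counts", {
  bil <- build_bilayer_model("POPC")
  kp <- kinetic_params(v = 3, D = 1, max_time = 1, seed = 20)
  tr <- simulate_insertion_trajectory(bil, kp)
  assigned <- assign_components(tr$lipid_atoms, component_map("POPC"))
  # generator manifest: per-lipid heavy-atom counts times 128 lipids
  counts <- table(assigned$bin)
  expect_equal(unname(counts["choline"]), 128 * 5)
  expect_equal(unname(counts["phosphate"]), 128 * 4)
  expect_equal(unname(counts["glycerol"]), 128 * 6)
  expect_equal(unname(counts["tail"]), 128 * 14)
})

test_that("single-pair geometry counts exactly at the cutoff", {
  lip <- tibble::tibble(atom_id = 1L, component = "phosphate",
                        leaflet = "upper", lipid = 1L,
                        x = 10, y = 10, z = 21.5)
  tr <- make_toy_traj(z = 18.5, dt = 0.1, lipid_atoms = lip)
  cc4 <- count_contacts(tr, cutoff = 4)
  expect_equal(cc4$count[cc4$bin == "phosphate"], 1)
  expect_equal(sum(cc4$count), 1)
  cc2 <- count_contacts(tr, cutoff = 2)
  expect_equal(sum(cc2$count), 0)
})

test_that("contact counting matches an all-pairs brute-force oracle", {
  set.seed(21)
  box <- c(x = 25, y = 25, z = 80)
  bins <- c("choline", "phosphate", "glycerol", "tail")
  for (f in 1:100) {
    n_lip <- 40
    lip <- tibble::tibble(
      atom_id = seq_len(n_lip),
      component = sample(bins, n_lip, replace = TRUE),
      leaflet = "upper", lipid = 1L,
      x = runif(n_lip, 0, 25), y = runif(n_lip, 0, 25),
      z = runif(n_lip, 10, 30)
    )
    offs <- matrix(rnorm(10 * 3), ncol = 3)
    tr <- make_toy_traj(z = 20, dt = 0.1, lipid_atoms = lip, box = box,
                        drug_xy = runif(2, 0, 25), drug_offsets = offs)
    cutoff <- runif(1, 2, 8)
    got <- count_contacts(tr, cutoff = cutoff)

    # naive O(n^2) double loop with minimum image in x and y
    dm <- meminsert:::drug_atom_coords(tr, 1)
    expected <- setNames(numeric(4), bins)
    for (a in seq_len(nrow(dm))) {
      for (b in seq_len(n_lip)) {
        dx <- dm[a, 1] - lip$x[b]; dx <- dx - 25 * round(dx / 25)
        dy <- dm[a, 2] - lip$y[b]; dy <- dy - 25 * round(dy / 25)
        dz <- dm[a, 3] - lip$z[b]
        if (sqrt(dx^2 + dy^2 + dz^2) <= cutoff) {
          expected[lip$component[b]] <- expected[lip$component[b]] + 1
        }
      }
    }
    expect_equal(setNames(got$count, got$bin)[bins], expected)
  }
})

test_that("counts are invariant to lattice translations", {
  set.seed(22)
  lip <- tibble::tibble(
    atom_id = 1:30, component = sample(c("phosphate", "tail"), 30, TRUE),
    leaflet = "upper", lipid = 1L,
    x = runif(30, 0, 20), y = runif(30, 0, 20), z = runif(30, 15, 22)
  )
  tr <- make_toy_traj(z = 18, dt = 0.1, lipid_atoms = lip,
                      box = c(x = 20, y = 20, z = 80),
                      drug_offsets = matrix(rnorm(9), ncol = 3))
  base <- count_contacts(tr, cutoff = 5)
  tr2 <- tr
  tr2$lipid_atoms$x <- tr2$lipid_atoms$x + 3 * 20  # shift by 3 lattice vectors
  tr2$lipid_atoms$y <- tr2$lipid_atoms$y - 20
  shifted <- count_contacts(tr2, cutoff = 5)
  expect_equal(base$count, shifted$count)
})

test_that("window selection validates against the trajectory span", {
  tr <- make_toy_traj(z = rep(20, 11), dt = 0.1)
  expect_error(count_contacts(tr, window = c(0, 5)), "outside")
  ok <- count_contacts(tr, window = c(0.2, 0.8))
  expect_equal(length(unique(ok$frame)), 7)
})

test_that("histogram percentages follow hand arithmetic and normalise", {
  counts <- tibble::tibble(
    frame = rep(1:2, each = 3), time_ns = rep(c(0, 1), each = 3),
    bin = rep(c("choline", "phosphate", "tail"), 2),
    count = c(10, 30, 5, 20, 30, 5)
  )
  h <- contact_histogram(counts)
  expect_equal(h$percentage[h$bin == "choline"], 30)
  expect_equal(h$percentage[h$bin == "phosphate"], 60)
  expect_equal(h$percentage[h$bin == "tail"], 10)
  expect_equal(sum(h$percentage), 100, tolerance = 1e-6)

  single <- contact_histogram(dplyr::mutate(counts, count = ifelse(bin == "tail", 3, 0)))
  expect_equal(single$percentage[single$bin == "tail"], 100)

  empty <- contact_histogram(dplyr::mutate(counts, count = 0))
  expect_true(attr(empty, "empty"))
  expect_true(all(empty$percentage == 0))
})

test_that("percentage normalisation holds over randomized inputs", {
  set.seed(23)
  for (i in 1:50) {
    counts <- tibble::tibble(
      frame = rep(1:5, each = 4), time_ns = rep(1:5, each = 4),
      bin = rep(c("a", "b", "c", "d"), 5),
      count = rpois(20, 3)
    )
    h <- contact_histogram(counts)
    if (!attr(h, "empty")) expect_equal(sum(h$percentage), 100, tolerance = 1e-6)
  }
})

test_that("a drug held at phosphate depth contacts phosphate the most", {
  bil <- build_bilayer_model("POPC")
  kp <- kinetic_params(v = 5, D = 0.5, max_time = 20, frame_interval = 0.2)
  tr <- simulate_insertion_trajectory(bil, kp, seed = 24,
                                      settle_depth = bil$phosphate_plane_upper)
  cc <- count_contacts(tr, cutoff = 4)
  h <- contact_histogram(cc)
  expect_equal(h$bin[which.max(h$percentage)], "phosphate")
})

test_that("early-window control flags a late descent into the tails", {
  bil <- build_bilayer_model("POPC")
  kp <- kinetic_params(v = 5, D = 0.5, max_time = 100, frame_interval = 0.5)
  sched <- tibble::tibble(time_ns = c(0, 60),
                          target_z = c(bil$phosphate_plane_upper - 1, 0))
  tr <- simulate_insertion_trajectory(bil, kp, seed = 25, depth_schedule = sched)
  wc <- windowed_comparison(tr, cutoff = 4, early_ns = 60)
  tail_full <- wc$full$percentage[wc$full$bin == "tail"]
  tail_early <- wc$early$percentage[wc$early$bin == "tail"]
  expect_gt(tail_full, tail_early)
  expect_equal(wc$differences$abs_diff[wc$differences$bin == "tail"],
               abs(tail_full - tail_early))

  # identity: early window equal to the full window
  wc2 <- windowed_comparison(tr, cutoff = 4, early_ns = 100)
  expect_equal(as.data.frame(wc2$full), as.data.frame(wc2$early))
  expect_true(all(wc2$differences$abs_diff == 0))
})

test_that("a stationary inserted drug gives a stable histogram over windows", {
  bil <- build_bilayer_model("POPC")
  kp <- kinetic_params(v = 8, D = 0.2, max_time = 80, frame_interval = 0.5)
  tr <- simulate_insertion_trajectory(bil, kp, seed = 26,
                                      settle_depth = bil$phosphate_plane_upper - 1)
  wc <- windowed_comparison(tr, cutoff = 4, early_ns = 60)
  expect_true(all(wc$differences$abs_diff < 10))
})
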