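test_that("cutting the terminal loop partitions the chain at a loop midpoint", {
  cut <- cut_terminal_loop(C_CHAIN)
  hr <- helix_ranges(C_CHAIN, "C")
  # interface fragment holds exactly the last two helices
  frag_res <- cut$interface_fragment$resi
  expect_true(all(seq(hr$start[5], hr$end[6]) %in% frag_res))
  expect_false(any(seq(hr$start[1], hr$end[4]) %in% frag_res))
  # cut point inside the loop preceding helix 5
  expect_gt(cut$cut_point, hr$end[4])
  expect_lt(cut$cut_point, hr$start[5])
  # partition: disjoint and complete
  all_res <- unique(C_CHAIN$resi)
  expect_setequal(c(cut$body$resi, frag_res), all_res)
  expect_length(intersect(cut$body$resi, frag_res), 0)

  two_helix <- truncate_c_subunit(TRI, 4) |> get_chain("C")
  expect_error(cut_terminal_loop(two_helix), "at least 3")
})

test_that("extension targets translate the body rigidly and fix the interface", {
  ext <- make_extension_target(ASM, d = 100, rho = 0)
  mv_key <- paste(ASM$chain, ASM$resi) %in%
    paste(ext$target$moved_selection$chain, ext$target$moved_selection$resi)
  before <- cbind(ASM$x, ASM$y, ASM$z)
  after <- cbind(ext$structure$x, ext$structure$y, ext$structure$z)
  # centroid displaced by exactly (0, 0, 100)
  expect_equal(colMeans(after[mv_key, ]) - colMeans(before[mv_key, ]),
               c(0, 0, 100), tolerance = 1e-10, ignore_attr = TRUE)
  # interface fragments and the whole partner ring bit-identical
  expect_identical(after[!mv_key, ], before[!mv_key, ])
  # rigidity of the moved selection
  withr::local_seed(2)
  idx <- which(mv_key)[sample(sum(mv_key), 40)]
  expect_lt(max(abs(dist(after[idx, ]) - dist(before[idx, ]))), 1e-8)
  # inverse transform restores the original
  restored <- after
  restored[mv_key, ] <- apply_transform(after[mv_key, , drop = FALSE],
                                        transform_inverse(ext$target$transform))
  expect_lt(max(abs(restored - before)), 1e-8)
})

test_that("the rotated target records its rotation and keeps five-fold closure", {
  ext <- make_extension_target(ASM, d = 50, rho = 25)
  expect_lt(abs(rotation_angle_about_axis(ext$target$transform,
                                          c(0, 0, 1)) - 25), 1e-6)
  # moved portions of the five C subunits stay five-fold symmetric
  face1 <- ext$structure[ext$structure$face == 1, ]
  class(face1) <- class(ext$structure)
  rep <- verify_symmetry(face1, 5, tol = 1e-6)
  expect_lt(rep$cyclic_closure_rmsd, 1e-6)

  ident <- make_extension_target(ASM, d = 0, rho = 0)
  expect_equal(ident$structure$x, ASM$x)
  expect_equal(ident$structure$z, ASM$z)

  expect_error(make_extension_target(ASM, d = -5), ">= 0")
})

test_that("contig specs look up the preset insert ranges and reject others", {
  presets <- list(list(25, 0, c(50, 150)), list(50, 0, c(100, 250)),
                  list(75, 0, c(150, 350)), list(100, 0, c(250, 400)),
                  list(50, 25, c(150, 350)))
  for (p in presets) {
    ext <- make_extension_target(ASM, d = p[[1]], rho = p[[2]])
    spec <- emit_contig_spec(ext$target, ASM)
    expect_equal(spec$insert_length_range, p[[3]])
  }
  ext60 <- make_extension_target(ASM, d = 60, rho = 0)
  expect_error(emit_contig_spec(ext60$target, ASM), "no preset")
  with_range <- emit_contig_spec(ext60$target, ASM, insert_range = c(120, 300))
  expect_equal(with_range$insert_length_range, c(120, 300))

  # reduced input: four body helices plus the two interface helices per C
  ext <- make_extension_target(ASM, d = 100, rho = 0)
  spec <- emit_contig_spec(ext$target, ASM)
  per_chain <- table(spec$reduced_input_selection$chain,
                     spec$reduced_input_selection$part)
  expect_true(all(per_chain[, "body"] == 4))
  expect_true(all(per_chain[, "interface"] == 2))
})

test_that("adjacency targets combine geometric contacts with requests", {
  # identity order, no insertion: adjacency equals the brute-force helix
  # contact map at 10 A
  at <- make_adjacency_target(C_CHAIN)
  hr <- helix_ranges(C_CHAIN, "C")
  ca <- C_CHAIN[C_CHAIN$atom == "CA", ]
  brute <- matrix(0L, nrow(hr), nrow(hr))
  for (i in seq_len(nrow(hr))) for (j in seq_len(nrow(hr))) {
    if (i == j) next
    a <- ca[ca$resi >= hr$start[i] & ca$resi <= hr$end[i], ]
    b <- ca[ca$resi >= hr$start[j] & ca$resi <= hr$end[j], ]
    dmin <- Inf
    for (k in seq_len(nrow(a))) {
      dmin <- min(dmin, min((b$x - a$x[k])^2 + (b$y - a$y[k])^2 +
                              (b$z - a$z[k])^2))
    }
    if (sqrt(dmin) < 10) brute[i, j] <- 1L
  }
  expect_identical(at$adjacency, brute)
  expect_identical(at$adjacency, t(at$adjacency))
  expect_true(all(diag(at$adjacency) == 0))

  # reversed first three helices with one inserted helix
  at2 <- make_adjacency_target(C_CHAIN, new_order = c(3, 2, 1, 7, 4, 5, 6),
                               new_helix_length = 14,
                               contacts = list(c(7, 1), c(7, 2)))
  expect_equal(dim(at2$adjacency), c(7, 7))
  expect_equal(sum(at2$adjacency[7, ]), 2)
  expect_setequal(which(at2$adjacency[7, ] == 1), c(1, 2))
  # reversing 1-3 invalidates the three loops touching them
  expect_equal(nrow(at2$deleted_loops), 3)
  expect_equal(at2$deleted_loops$after_helix, 1:3)

  expect_error(make_adjacency_target(C_CHAIN, contacts = list(c(2, 2))),
               "itself")
  expect_error(make_adjacency_target(C_CHAIN, new_order = c(1, 1, 2, 3, 4, 5, 6)),
               "permutation")
})

test_that("diffusion job manifests round-trip with their spec files", {
  ext <- make_extension_target(ASM, d = 50, rho = 0)
  jobs1 <- emit_diffusion_job(ext$target)
  expect_equal(nrow(jobs1), 1)
  expect_equal(jobs1$n_backbones, 100L)

  targets <- lapply(c(25, 50, 75, 100), function(d)
    make_extension_target(ASM, d = d)$target)
  targets[[5]] <- make_extension_target(ASM, d = 50, rho = 25)$target
  d <- withr::local_tempdir()
  jobs <- emit_diffusion_job(targets, dir = d)
  expect_equal(nrow(jobs), 5)
  expect_true(all(file.exists(jobs$spec_path)))
  f <- file.path(d, "manifest.tsv")
  write_diffusion_manifest(jobs, f)
  expect_equal(tibble::as_tibble(read_diffusion_manifest(f)),
               tibble::as_tibble(jobs))

  at <- make_adjacency_target(C_CHAIN, new_order = c(3, 2, 1, 7, 4, 5, 6),
                              contacts = list(c(7, 1)))
  fm <- file.path(d, "adj.txt")
  write_adjacency_matrix(at, fm)
  lines <- readLines(fm)
  expect_length(lines, 8)  # header + 7 rows
  m <- as.matrix(read.table(fm, skip = 1))
  expect_equal(unname(m), unname(at$adjacency), ignore_attr = TRUE)
})
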