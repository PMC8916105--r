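test_that("morphological closing handles degenerate masks", {
  mesh <- fix_mesh()
  nv <- n_vertices(mesh)
  empty <- lesion_mask("E", integer(nv), "left", allow_empty = TRUE)
  expect_equal(sum(close_mask(empty, mesh, 1)$indicator), 0)
  full <- lesion_mask("F", rep(1L, nv), "left")
  expect_equal(close_mask(full, mesh, 2)$indicator, rep(1L, nv))
})

test_that("closing fills the deleted centre of a geodesic disc", {
  mesh <- fix_mesh()
  disc <- geodesic_disc(mesh, 1, 3)
  ind <- integer(n_vertices(mesh))
  ind[disc] <- 1L
  ind[1] <- 0L                       # punch out the centre vertex
  holed <- lesion_mask("H", ind, "left")
  closed <- close_mask(holed, mesh, 1)
  expect_equal(closed$indicator[1], 1L)
  # matches the brute-force set oracle exactly
  oracle <- bf_close(which(ind == 1L), fix_nbrs(), 1)
  expect_equal(which(closed$indicator == 1L), oracle)
})

test_that("closing is extensive, monotone and idempotent (vs oracle)", {
  mesh <- fix_mesh()
  nbrs <- fix_nbrs()
  set.seed(11)
  for (rep_i in 1:8) {
    k <- sample(1:2, 1)
    a <- random_mask_vec(mesh)
    if (sum(a) == 0) a[1] <- 1L
    b <- as.integer(a | random_mask_vec(mesh, 0.1))   # a subset of b
    ma <- lesion_mask("A", a, "left")
    mb <- lesion_mask("B", b, "left")
    ca <- close_mask(ma, mesh, k)
    cb <- close_mask(mb, mesh, k)
    expect_true(all(ca$indicator >= a))                       # extensive
    expect_true(all(cb$indicator >= ca$indicator))            # monotone
    expect_equal(close_mask(ca, mesh, k)$indicator,
                 ca$indicator)                                # idempotent
    expect_equal(which(ca$indicator == 1L),
                 bf_close(which(a == 1L), nbrs, k))           # oracle
  }
})

test_that("lesion size is the percentage of hemisphere vertices", {
  mesh <- fix_mesh()
  nv <- n_vertices(mesh)
  expect_equal(lesion_size_pct(lesion_mask("F", rep(1L, nv), "left")), 100)
  expect_equal(
    lesion_size_pct(lesion_mask("E", integer(nv), "left",
                                allow_empty = TRUE)), 0)
  ind <- integer(1000)
  ind[1:50] <- 1L
  expect_equal(lesion_size_pct(structure(
    list(patient_id = "X", hemisphere = "left", indicator = ind),
    class = "lesion_mask")), 5)
  # closing never shrinks a lesion
  m <- disc_mask(mesh, 5, 2)
  expect_gte(lesion_size_pct(close_mask(m, mesh, 1)), lesion_size_pct(m))
})

make_lobe_parc <- function(nv) {
  # labels: 1 frontal, 2 parietal, 3 cingulate, 4 insula over vertex blocks
  labels <- rep(1L, nv)
  labels[41:80] <- 2L
  labels[81:120] <- 3L
  labels[121:nv] <- 4L
  parcellation(labels, c("f1", "p1", "c1", "i1"),
               c(f1 = "frontal", p1 = "parietal", c1 = "cingulate",
                 i1 = "insula"),
               eloquent_bilateral = character(0),
               eloquent_left_only = character(0))
}

test_that("lobe assignment follows the majority and reassignment rules", {
  nv <- n_vertices(fix_mesh())
  parc <- make_lobe_parc(nv)
  mk <- function(idx) {
    ind <- integer(nv)
    ind[idx] <- 1L
    lesion_mask("L", ind, "left")
  }
  expect_equal(assign_lobe(mk(1:10), parc), "frontal")
  # 60% cingulate / 40% frontal -> reassigned to frontal
  expect_equal(assign_lobe(mk(c(81:86, 1:4)), parc), "frontal")
  # 50/50 frontal/parietal tie -> frontal by fixed order
  expect_equal(assign_lobe(mk(c(1:5, 41:45)), parc), "frontal")
  # lesion entirely in cingulate keeps the small lobe
  expect_equal(assign_lobe(mk(85:90), parc), "cingulate")
  expect_error(assign_lobe(mk(integer(0)), parc), "empty")
})

test_that("lobe assignment never yields cingulate/insula when another lobe
           is touched", {
  nv <- n_vertices(fix_mesh())
  parc <- make_lobe_parc(nv)
  set.seed(21)
  for (i in 1:20) {
    idx <- sample.int(nv, sample(3:30, 1))
    ind <- integer(nv)
    ind[idx] <- 1L
    lobe <- assign_lobe(lesion_mask("R", ind, "left"), parc)
    touched <- unique(lobe_per_vertex(parc)[idx])
    if (any(!touched %in% c("cingulate", "insula")))
      expect_false(lobe %in% c("cingulate", "insula"))
  }
})

test_that("eloquent mask is hemisphere-aware and validates labels", {
  parc <- fix_parc()
  left <- eloquent_mask(parc, "left")
  right <- eloquent_mask(parc, "right")
  expect_true(sum(left) > 0)
  expect_true(all(right <= left))    # language labels are left-only
  expect_true(sum(left) > sum(right))
  nv <- n_vertices(fix_mesh())
  no_precentral <- parcellation(rep(1L, nv), "other",
                                c(other = "frontal"))
  expect_error(eloquent_mask(no_precentral, "left"), "precentral")
})

test_that("eloquent overlap is the lesional fraction inside the mask", {
  parc <- fix_parc()
  elo <- eloquent_mask(parc, "left")
  nv <- length(elo)
  inside <- which(elo == 1L)
  outside <- which(elo == 0L)
  mk <- function(idx) {
    ind <- integer(nv)
    ind[idx] <- 1L
    lesion_mask("O", ind, "left")
  }
  expect_equal(eloquent_overlap(mk(outside[1:10]), elo), 0)
  expect_equal(eloquent_overlap(mk(inside[1:10]), elo), 1)
  expect_equal(eloquent_overlap(mk(c(inside[1:20], outside[1:20])), elo),
               0.5)
  expect_error(eloquent_overlap(mk(integer(0)), elo))
  # invariant to relabeling of non-eloquent parcels
  relabeled <- parc
  swap <- which(!parc$label_names %in%
                  c(parc$eloquent_bilateral, parc$eloquent_left_only))
  relabeled$label_names[swap] <- paste0("renamed_", swap)
  names(relabeled$lobe_of_label) <- relabeled$label_names
  elo2 <- eloquent_mask(relabeled, "left")
  expect_equal(elo2, elo)
})

test_that("pooling to the left re-tags right masks index-identically", {
  nv <- n_vertices(fix_mesh())
  ind <- integer(nv)
  ind[c(3, 9, 14)] <- 1L
  l <- lesion_mask("L", ind, "left")
  r <- lesion_mask("R", ind, "right")
  pooled <- pool_to_left(list(l, r))
  expect_identical(pooled[[1]], l)
  expect_equal(pooled[[2]]$hemisphere, "left")
  expect_equal(pooled[[2]]$indicator, ind)
  expect_true(all(vapply(pooled, function(m) m$hemisphere,
                         character(1)) == "left"))
})
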