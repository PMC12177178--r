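phantom_world <- local({
  cfg <- phantom_config(n_collateral_voxels = 0L, noise_rate = 0, seed = 0)
  list(cfg = cfg,
       atlas = generate_axon_phantom(cfg)$atlas,
       frame = phantom_frame(cfg))
})

test_that("generated neurons are classified into their true class", {
  trig <- c("PrV", "SpVi", "SpVc")
  for (cl in c("ipsi", "contra", "bilateral")) {
    for (s in 1:8) {
      g <- generate_neuron_swc(phantom_world$cfg, cl, seed = s)
      res <- classify_neuron(g$tree, phantom_world$frame, phantom_world$atlas, trig)
      expect_equal(res$class, cl)
    }
  }
})

test_that("neurons terminating outside the listed regions classify as none", {
  g <- generate_neuron_swc(phantom_world$cfg, "ipsi", seed = 4)
  # Restrict the target list to regions the ipsi branches never enter here:
  res <- classify_neuron(g$tree, phantom_world$frame, phantom_world$atlas,
                         regions = "VII")
  expect_equal(res$class, "none")
  expect_equal(res$n_terminals_ipsi + res$n_terminals_contra, 0)
})

test_that("classification is invariant under SWC node reordering", {
  g <- generate_neuron_swc(phantom_world$cfg, "bilateral", seed = 6)
  ref <- classify_neuron(g$tree, phantom_world$frame, phantom_world$atlas,
                         c("PrV", "SpVi", "SpVc"))
  set.seed(1)
  shuffled <- g$tree[sample(nrow(g$tree)), ]
  rownames(shuffled) <- NULL
  class(shuffled) <- c("neuron_tree", "data.frame")
  res <- classify_neuron(shuffled, phantom_world$frame, phantom_world$atlas,
                         c("PrV", "SpVi", "SpVc"))
  expect_equal(res$class, ref$class)
  expect_equal(res$n_terminals_ipsi, ref$n_terminals_ipsi)
})

test_that("a branchless tree warns and classifies as none", {
  tree <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                     radius = 1, parent = -1L)
  class(tree) <- c("neuron_tree", "data.frame")
  expect_warning(res <- classify_neuron(tree, phantom_world$frame,
                                        phantom_world$atlas, "PrV"),
                 "no branches")
  expect_equal(res$class, "none")
})

test_that("soma counting assigns reference-channel somas by hemisphere", {
  fr <- phantom_world$frame
  st <- generate_soma_table(7, 1, 0, seed = 11)
  far <- data.frame(x_um = 2900, y_um = 100, z_um = 390, channel = "B")
  sc <- count_somas(rbind(st, far), fr, pair_radius_um = 10)
  expect_equal(sc$n_contra, 7)
  expect_equal(sc$n_ipsi, 1)
  expect_equal(sc$n_double, 0)
  expect_equal(sc$contralateral_percentage, 87.5)
})

test_that("double-label pairing is greedy, cross-channel and radius-bounded", {
  two <- data.frame(x_um = c(1000, 1003), y_um = c(100, 104), z_um = c(200, 200),
                    channel = c("A", "B"))
  fr <- phantom_world$frame
  expect_equal(count_somas(two, fr, pair_radius_um = 10)$n_double, 1)
  expect_equal(count_somas(two, fr, pair_radius_um = 2)$n_double, 0)

  set.seed(33)
  for (rep in 1:10) {
    nA <- sample(0:6, 1); nB <- sample(0:6, 1)
    somas <- data.frame(x_um = runif(nA + nB, 0, 3000),
                        y_um = runif(nA + nB, 0, 2000),
                        z_um = runif(nA + nB, 0, 3000),
                        channel = c(rep("A", nA), rep("B", nB)))
    sc <- count_somas(somas, fr, pair_radius_um = 500)
    expect_lte(sc$n_double, min(nA, nB))
    # Unpaired reference-channel somas are all assigned a hemisphere
    # (no exclusion band on this frame, no exact on-plane coordinates).
    expect_equal(sc$n_contra + sc$n_ipsi, nA - sc$n_double)
  }
  expect_error(count_somas(data.frame(x_um = 1, y_um = 1, z_um = 1,
                                      channel = "C"), fr),
               "unknown channel")
})
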