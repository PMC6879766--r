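test_that("AMSD matches hand computation and affine invariance", {
  v <- c(1, 3, 0, 2)
  l <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(amsd(v, l), 1 / sqrt(1.25), tolerance = 1e-13)
  # identical class distributions
  expect_equal(amsd(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 0)
  # invariance under positive affine maps
  set.seed(50)
  for (i in 1:20) {
    x <- rnorm(200)
    lab <- runif(200) < 0.3
    a <- runif(1, 0.1, 10)
    b <- rnorm(1, 0, 5)
    expect_equal(amsd(a * x + b, lab), amsd(x, lab), tolerance = 1e-10)
  }
  # degenerate cases signal and return NA
  expect_warning(s <- amsd(c(1, 2), c(TRUE, TRUE)), "one class")
  expect_true(is.na(s))
  expect_warning(s <- amsd(c(1, 1, 1), c(TRUE, FALSE, TRUE)), "zero")
  expect_true(is.na(s))
})

test_that("the catalogue has the full parameter grid", {
  cat_ <- transformation_catalogue()
  counts <- table(vapply(cat_, function(s) s$name, ""))
  expect_equal(as.integer(counts[c(
    "winsor", "quantile_norm", "time_shift", "roll_mad", "roll_sd",
    "roll_mean", "roll_median", "lpf", "subtract_median", "hpf",
    "exponential"
  )]), c(2L, 3L, 2L, 12L, 12L, 12L, 12L, 3L, 12L, 3L, 2L))
  expect_length(cat_, 86)
  for (s in cat_) {
    expect_equal(s$group, unname(GROUP_ORACLE[s$name]))
    expect_setequal(s$input_groups, GRAPH_ORACLE[[s$name]])
  }
})

test_that("successor sets follow the input-group graph", {
  all_names <- unique(vapply(transformation_catalogue(), function(s) s$name, ""))
  # empty chain: every transformation lists group 0
  succ0 <- valid_successor_specs(NULL)
  expect_setequal(unique(vapply(succ0, function(s) s$name, "")), all_names)
  mk_chain <- function(name) {
    structure(
      list(specs = list(spec_by_name(name)), achieved_amsd = 1),
      class = "transformation_chain"
    )
  }
  # after Winsor (group 1): exactly the transformations of groups 2, 3, 4
  succ1 <- vapply(valid_successor_specs(mk_chain("winsor")), function(s) s$name, "")
  expect_setequal(unique(succ1), names(GROUP_ORACLE)[GROUP_ORACLE %in% 2:4])
  # after Log (group 9): Winsor plus the group-4 family
  succ9 <- vapply(valid_successor_specs(mk_chain("log")), function(s) s$name, "")
  expect_setequal(
    unique(succ9),
    c("winsor", "boxcox", "histogram", "quantile_norm", "tukey_ladder")
  )
  # depth cap
  deep <- structure(
    list(specs = rep(list(spec_by_name("winsor")), 5)),
    class = "transformation_chain"
  )
  expect_length(valid_successor_specs(deep), 0)
})

test_that("individual transformations match hand computations", {
  expect_equal(
    apply_transformation(c(1, 2, 4), spec_by_name("median_removal")),
    c(-1, 0, 2)
  )
  expect_equal(
    apply_transformation(c(1, 2, 3), spec_by_name("zscore")),
    c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12
  )
  # time shift +1 pads at the head, -1 at the tail
  expect_equal(
    apply_transformation(c(5, 6, 7), spec_by_name("time_shift", 2)), # +1
    c(NA, 5, 6)
  )
  expect_equal(
    apply_transformation(c(5, 6, 7), spec_by_name("time_shift", 1)), # -1
    c(6, 7, NA)
  )
  # winsor clipping at the 5-95 percentiles
  x <- 1:100
  w <- apply_transformation(x, spec_by_name("winsor", 2))
  expect_equal(range(w), unname(quantile(x, c(0.05, 0.95))))
  # percentile maps to [0, 1]
  p <- apply_transformation(c(10, 30, 20), spec_by_name("percentile"))
  expect_equal(p, c(0, 1, 0.5))
  # amplitude scaling by the maximum absolute value
  expect_equal(
    apply_transformation(c(-4, 2), spec_by_name("amplitude")), c(-1, 0.5)
  )
  # missing values propagate through windowed operators
  x <- c(1, NA, 3, 4, 5, 6, 7, 8)
  rm_ <- apply_transformation(x, spec_by_name("roll_mean")) # 7, backward
  expect_true(is.na(rm_[2]))
  expect_false(anyNA(rm_[c(1, 3:8)]))
})

test_that("quantile normalisation hits the reference quantiles at rank/(n+1)", {
  x <- c(3, 1, 2)
  qn <- apply_transformation(x, spec_by_name("quantile_norm", 1)) # normal
  expect_equal(qn, qnorm(c(3, 1, 2) / 4))
  qu <- apply_transformation(x, spec_by_name("quantile_norm", 3)) # uniform
  expect_equal(qu, c(0.75, 0.25, 0.5))
})

test_that("randomly grown chains are always graph-legal and short", {
  set.seed(51)
  for (i in 1:300) {
    chain <- structure(
      list(specs = list(), achieved_amsd = 0),
      class = "transformation_chain"
    )
    depth <- sample(0:5, 1)
    for (d in seq_len(depth)) {
      succ <- valid_successor_specs(chain)
      if (!length(succ)) break
      chain$specs[[length(chain$specs) + 1L]] <- succ[[sample.int(length(succ), 1)]]
    }
    expect_lte(length(chain$specs), 5)
    prev_group <- 0
    for (s in chain$specs) {
      expect_true(prev_group %in% GRAPH_ORACLE[[s$name]])
      prev_group <- GROUP_ORACLE[[s$name]]
    }
  }
})

test_that("depth-1 greedy equals exhaustive enumeration", {
  set.seed(52)
  for (trial in 1:5) {
    n_rec <- 3
    values <- numeric(0)
    labels <- logical(0)
    rid <- character(0)
    for (r in 1:n_rec) {
      lab <- runif(60) < 0.35
      v <- rnorm(60) + ifelse(lab, runif(1, 0.3, 1), 0)
      values <- c(values, v)
      labels <- c(labels, lab)
      rid <- c(rid, rep(paste0("r", r), 60))
    }
    # independent exhaustive oracle over every catalogue spec
    rec_index <- split(seq_along(values), rid)
    best <- suppressWarnings(amsd(values, labels))
    best_id <- 0L
    for (s in transformation_catalogue()) {
      out <- values
      for (g in rec_index) out[g] <- apply_transformation(values[g], s)
      sc <- suppressWarnings(amsd(out, labels))
      if (!is.na(sc) && sc > best) {
        best <- sc
        best_id <- s$id
      }
    }
    chain <- suppressWarnings(
      optimise_feature(values, labels, rid, max_depth = 1L)
    )
    expect_equal(chain$achieved_amsd, best, tolerance = 1e-12)
    if (best_id > 0L) expect_equal(chain$specs[[1]]$id, best_id)
  }
})

test_that("dispersion-carried class signal selects a dispersion operator", {
  set.seed(53)
  values <- numeric(0)
  labels <- logical(0)
  rid <- character(0)
  for (r in 1:3) {
    lab <- rep(rep(c(FALSE, TRUE), each = 10), 6)
    v <- rnorm(120, 0, ifelse(lab, 3, 0.5)) # signal in local variance only
    values <- c(values, v)
    labels <- c(labels, lab)
    rid <- c(rid, rep(paste0("r", r), 120))
  }
  chain <- suppressWarnings(optimise_feature(values, labels, rid, max_depth = 1L))
  expect_equal(length(chain$specs), 1L)
  expect_true(chain$specs[[1]]$name %in% c("roll_mad", "roll_sd", "abs_value"))
})

test_that("greedy chains improve monotonically and replay exactly", {
  set.seed(54)
  values <- numeric(0)
  labels <- logical(0)
  rid <- character(0)
  for (r in 1:4) {
    lab <- runif(80) < 0.3
    v <- exp(rnorm(80) + ifelse(lab, 0.8, 0)) # lognormal: transformations help
    values <- c(values, v)
    labels <- c(labels, lab)
    rid <- c(rid, rep(paste0("r", r), 80))
  }
  chain <- suppressWarnings(optimise_feature(values, labels, rid))
  expect_lte(length(chain$specs), 5)
  expect_true(all(diff(chain$amsd_trace) > 0))
  expect_gte(chain$achieved_amsd, suppressWarnings(amsd(values, labels)))
  replay <- apply_chain(values, rid, chain)
  expect_equal(
    suppressWarnings(amsd(replay, labels)), chain$achieved_amsd,
    tolerance = 1e-12
  )
})

test_that("degenerate features yield an empty chain with zero score", {
  ch <- optimise_feature(rep(1, 40), rep(c(TRUE, FALSE), 20), rep("r", 40))
  expect_length(ch$specs, 0)
  expect_equal(ch$achieved_amsd, 0)
})

test_that("chains serialise to JSON and back", {
  set.seed(55)
  v <- rnorm(120)
  l <- runif(120) < 0.4
  v[l] <- v[l] + 1
  ch <- suppressWarnings(
    optimise_features(
      tibble::tibble(record_id = rep(c("a", "b"), each = 60), epoch = rep(0:59, 2), f = v),
      l,
      max_depth = 2
    )
  )
  path <- withr::local_tempfile(fileext = ".json")
  chains_to_json(ch, path)
  back <- chains_from_json(path)
  expect_equal(back$f$achieved_amsd, ch$f$achieved_amsd)
  expect_equal(
    apply_chain(v, rep(c("a", "b"), each = 60), back$f),
    apply_chain(v, rep(c("a", "b"), each = 60), ch$f)
  )
})
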