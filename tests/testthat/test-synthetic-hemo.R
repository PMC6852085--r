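test_that("identical seeds give bit-identical traces", {
  a <- default_scenario(noise_sd = 1.5, seed = 42)
  b <- default_scenario(noise_sd = 1.5, seed = 42)
  expect_identical(a$rvp$y, b$rvp$y)
  expect_identical(a$pap$y, b$pap$y)
  c <- default_scenario(noise_sd = 1.5, seed = 43)
  expect_false(identical(a$rvp$y, c$rvp$y))
})

test_that("clamped-valve peak equals the closed form Emax*(Ved - V0)", {
  expect_equal(clamp_isovolumic(elastance_params(emax = 2, ved = 60, v0 = 10)),
               100)
  expect_equal(clamp_isovolumic(elastance_params(emax = 0.5, ved = 40, v0 = 10)),
               15)
  # simulated clamped beat reaches the closed form within grid tolerance
  par <- elastance_params(emax = 1.2, hr = 136)
  sc <- simulate_beats(par, afterload_params(),
                       sim_config(n_beats = 3, seed = 1),
                       clamp_valve = TRUE)
  expect_lt(abs(max(sc$rvp$y) - clamp_isovolumic(par)) / clamp_isovolumic(par),
            1e-3)
  expect_true(sc$non_ejecting)
})

test_that("clamped peak strictly exceeds the ejecting peak", {
  for (emax in c(0.6, 1.5, 3)) {
    par <- elastance_params(emax = emax, hr = 120)
    sc <- default_scenario(emax = emax, hr = 120)
    expect_gt(clamp_isovolumic(par), max(sc$rvp$y))
  }
})

test_that("per-beat flow integral matches Ved - Ves (conservation)", {
  sc <- default_scenario(n_beats = 10)
  fs <- sc$flow$fs
  spb <- round(sc$params$t_beat * fs)
  for (b in seq_len(nrow(sc$truth))) {
    idx <- (b - 1) * spb + seq_len(spb)
    sv_int <- wf_integrate(sc$flow, idx)
    expect_equal(sv_int, sc$truth$sv[b], tolerance = 0.02)
  }
})

test_that("stroke volume decreases and mean PA pressure rises with Rp", {
  rps <- c(0.3, 0.6, 1.0, 1.6)
  svs <- numeric(0); paps <- numeric(0)
  for (rp in rps) {
    sc <- default_scenario(emax = 1.2, rp = rp, n_beats = 6)
    svs <- c(svs, median(sc$truth$sv))
    paps <- c(paps, mean(sc$pap$y))
  }
  expect_true(all(diff(svs) < 0))
  expect_true(all(diff(paps) > 0))
})

test_that("isovolumic peak is strictly increasing in Emax", {
  pk <- vapply(c(0.5, 1, 2, 3), function(e)
    clamp_isovolumic(elastance_params(emax = e)), numeric(1))
  expect_true(all(diff(pk) > 0))
})

test_that("too-weak contraction yields a non-ejecting flag, not an error", {
  # peak generated pressure below the windkessel charge pressure
  sc <- simulate_beats(elastance_params(emax = 0.2, ved = 30, v0 = 10),
                       afterload_params(pd0 = 30),
                       sim_config(n_beats = 3, seed = 1, n_transient = 0))
  expect_true(sc$non_ejecting)
})

test_that("non-convergent charging fails loudly", {
  expect_error(
    simulate_beats(elastance_params(emax = 1, hr = 136),
                   afterload_params(rp = 5, c_art = 20),
                   sim_config(n_beats = 2, seed = 1, max_transient = 6L)),
    "non-convergent")
})

test_that("Ct tables reproduce their design exactly without noise", {
  d0 <- ct_design(fold = c(g1 = 1, g2 = 1), ct_sd = 0, load_sd = 0)
  rel <- normalize_ddct(generate_ct_table(d0))
  expect_equal(rel$rel, rep(1, nrow(rel)))

  d2 <- ct_design(fold = c(g1 = 2), ct_sd = 0, load_sd = 0.7)
  tab <- generate_ct_table(d2)
  rel <- normalize_ddct(tab)
  expect_equal(rel$rel[rel$group == "CTEPH"], rep(2, d2$n_cteph))
  # reference genes carry the loading shift: raw CTEPH target Ct is one
  # cycle below control after reference correction
  ref <- tapply(tab$ct[tab$gene %in% d2$ref_genes],
                tab$sample_id[tab$gene %in% d2$ref_genes], mean)
  dct <- tab$ct[tab$gene == "g1"] - ref[tab$sample_id[tab$gene == "g1"]]
  grp <- tab$group[tab$gene == "g1"]
  expect_equal(unname(mean(dct[grp == "control"]) - mean(dct[grp == "CTEPH"])),
               1)
})

test_that("cohort generation is deterministic and directionally correct", {
  a <- generate_cohort(n_control = 2, n_cteph = 2, seed = 9, n_beats = 6)
  b <- generate_cohort(n_control = 2, n_cteph = 2, seed = 9, n_beats = 6)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  expect_identical(a$scenarios[["C01"]]$rest$rvp$y,
                   b$scenarios[["C01"]]$rest$rvp$y)
  # by construction the control arm gains more contractility than
  # afterload with exercise, the CTEPH arm does not
  tr <- a$truth
  gain <- function(g, f) {
    x <- tr[tr$group == g, ]
    mean(x[[f]][x$condition == "exercise"] / x[[f]][x$condition == "rest"])
  }
  expect_gt(gain("control", "emax"), gain("CTEPH", "emax"))
  expect_gt(gain("CTEPH", "rp"), 0.9)
})
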