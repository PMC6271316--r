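mv_dna <- 6966 * 0.55   # strand molar mass x partial specific volume, mL/mol

test_that("baseline chaining isolates the solute pulse heat", {
  q <- gen_ppc_trace(-0.106, Tm = 340.35)
  truth <- attr(q, "truth")
  cc <- ppc_baseline_chain(q)
  samp <- q[[4]]
  # oracle: invert the expansion relation with the injected alpha_s truth
  a_o <- (q[[2]]$dQ - q[[1]]$dQ) / (samp$T * samp$dP * 5e-7)
  dQ_expected <- (a_o - truth$alpha_s) * samp$T * samp$dP *
    (samp$m_s * samp$V_s * 1e-6)
  expect_lt(max(abs(cc$dQ - dQ_expected)), 1e-9)
  # sample identical to buffer/buffer corrects to exactly zero
  q0 <- q
  q0[[4]] <- ppc_scan(q[[3]]$T, q[[3]]$dQ, q[[3]]$dP, "sample_buffer",
                      m_s = samp$m_s, V_s = samp$V_s)
  expect_equal(max(abs(ppc_baseline_chain(q0)$dQ)), 0)
})

test_that("reference scans on an offset grid are interpolated consistently", {
  q <- gen_ppc_trace(-0.106, Tm = 340.35)
  aligned <- ppc_baseline_chain(q)
  shift <- function(s, role) {
    Ts <- s$T + 0.5
    keep <- Ts <= max(s$T)
    ppc_scan(Ts[keep], approx(s$T, s$dQ, xout = Ts[keep])$y, s$dP, role)
  }
  q2 <- list(shift(q[[1]], "water_water"), shift(q[[2]], "buffer_water"),
             shift(q[[3]], "buffer_buffer"), q[[4]])
  offset <- ppc_baseline_chain(q2)
  common <- aligned$T %in% offset$T
  expect_lt(max(abs(offset$dQ - aligned$dQ[common])), 1e-8)
})

test_that("chaining validates roles and grid overlap", {
  q <- gen_ppc_trace(-0.1, Tm = 340)
  expect_error(ppc_baseline_chain(q[1:3]), "missing")
  q2 <- q
  q2[[1]] <- ppc_scan(q[[1]]$T + 500, q[[1]]$dQ, q[[1]]$dP, "water_water")
  expect_error(ppc_baseline_chain(q2), "overlap")
})

test_that("the expansion-coefficient relation is applied pointwise in SI", {
  Tg <- seq(290, 300, by = 1)
  mk <- function(dQ) ppc_scan(Tg, rep(dQ, length(Tg)), psi_to_pa(70),
                              "sample_buffer", m_s = 1e-3, V_s = 0.5)
  # zero heat leaves the solvent trace untouched
  a <- alpha_solute(mk(0), alpha_o = 2.5e-4)
  expect_equal(a$alpha_s, rep(2.5e-4, length(Tg)))
  # dQ = 7.2e-5 J, T = 298.15 K, dP = 4.826e5 Pa, m_s V_s = 5e-10 m^3
  # -> correction = 1.0008e-3 1/K (independent closed-form evaluation)
  s <- ppc_scan(c(298.15, 299.15), c(7.2e-5, 0), 4.826e5, "sample_buffer",
                m_s = 1e-3, V_s = 0.5)
  a2 <- alpha_solute(s, alpha_o = 0)
  expect_equal(a2$alpha_s[1], -1.0008e-3, tolerance = 1e-4)
  # halving with doubled pressure step; linear in dQ
  s2 <- ppc_scan(c(298.15, 299.15), c(7.2e-5, 0), 2 * 4.826e5,
                 "sample_buffer", m_s = 1e-3, V_s = 0.5)
  expect_equal(alpha_solute(s2, alpha_o = 0)$alpha_s[1], a2$alpha_s[1] / 2)
  s3 <- ppc_scan(c(298.15, 299.15), 3 * c(7.2e-5, 0), 4.826e5,
                 "sample_buffer", m_s = 1e-3, V_s = 0.5)
  expect_equal(alpha_solute(s3, alpha_o = 0)$alpha_s[1], 3 * a2$alpha_s[1])
})

test_that("a trace equal to its baseline integrates to zero volume", {
  Tg <- seq(278.15, 393.15, by = 1)
  flat <- structure(list(T = Tg, alpha_s = 3e-4 + 1e-7 * (Tg - 300)),
                    class = "expansion_curve")
  r <- delta_volume(flat, c(315.35, 365.35), molar_volume = mv_dna)
  expect_lt(abs(r$delta_V), 1e-6)
})

test_that("the full chain recovers the published volume changes within 1%", {
  cases <- list(c(htel$mer22$dV, htel$mer22$Tm_tot),
                c(htel$mer23$dV, htel$mer23$Tm_tot),
                c(htel$mer24$dV, htel$mer24$Tm_tot))
  for (cs in cases) {
    Tm <- celsius_to_kelvin(cs[2])
    q <- gen_ppc_trace(cs[1], Tm = Tm)
    ac <- alpha_solute(ppc_baseline_chain(q))
    r <- delta_volume(ac, c(Tm - 25, Tm + 25), molar_volume = mv_dna)
    expect_lt(rel_err(r$delta_V, cs[1]), 0.01)
  }
})

test_that("volume recovery holds across signs and magnitudes", {
  for (dv in c(-0.3, -0.05, 0.12, 0.3)) {
    q <- gen_ppc_trace(dv, Tm = 335)
    ac <- alpha_solute(ppc_baseline_chain(q))
    r <- delta_volume(ac, c(310, 360), molar_volume = mv_dna)
    expect_lt(rel_err(r$delta_V, dv), 0.01)
  }
})

test_that("mirroring the peak flips the sign of the volume change", {
  q <- gen_ppc_trace(-0.12, Tm = 335)
  ac <- alpha_solute(ppc_baseline_chain(q))
  r <- delta_volume(ac, c(310, 360), molar_volume = mv_dna)
  # mirror the trace about its progress baseline by regenerating with +0.12
  qm <- gen_ppc_trace(0.12, Tm = 335)
  am <- alpha_solute(ppc_baseline_chain(qm))
  rm_ <- delta_volume(am, c(310, 360), molar_volume = mv_dna)
  expect_equal(rm_$delta_V, -r$delta_V, tolerance = 1e-3)
})

test_that("the volume integral ignores constant offsets in alpha_s", {
  q <- gen_ppc_trace(-0.106, Tm = 340.35)
  ac <- alpha_solute(ppc_baseline_chain(q))
  shifted <- structure(list(T = ac$T, alpha_s = ac$alpha_s + 5e-4),
                       class = "expansion_curve")
  r1 <- delta_volume(ac, c(315.35, 365.35), molar_volume = mv_dna)
  r2 <- delta_volume(shifted, c(315.35, 365.35), molar_volume = mv_dna)
  expect_equal(r1$delta_V, r2$delta_V, tolerance = 1e-9)
})

test_that("delta_volume validates its window and flanks", {
  q <- gen_ppc_trace(-0.1, Tm = 335)
  ac <- alpha_solute(ppc_baseline_chain(q))
  expect_error(delta_volume(ac, c(270, 360), mv_dna), "inside")
  expect_error(delta_volume(ac, c(279.15, 360), mv_dna), "flanking")
  expect_error(delta_volume(ac, c(310, 360), -1), "positive")
})
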