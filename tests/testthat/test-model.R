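test_that("reference model scales to the subject and conserves mass", {
  m <- build_reference_model(77.8, 1.81)
  expect_equal(total_mass(m), 77.8, tolerance = 1e-12)
  expect_equal(m$variant, "healthy")
  # identity scaling: unit mass/height reproduce the raw fractions
  m1 <- build_reference_model(1, 1)
  ref <- reference_anthropometry()
  expect_equal(m1$segments$thigh_il$mass, ref$mass_frac[ref$segment == "thigh"])
  expect_equal(m1$segments$shank_cl$length, ref$len_frac[ref$segment == "shank"])
  # healthy variant is bilaterally symmetric
  for (seg in c("thigh", "shank", "foot")) {
    il <- m$segments[[paste0(seg, "_il")]]
    cl <- m$segments[[paste0(seg, "_cl")]]
    expect_identical(il[c("mass", "length", "com_offset", "inertia_zz")],
                     cl[c("mass", "length", "com_offset", "inertia_zz")])
  }
  expect_error(build_reference_model(-1, 1.8), "must be > 0")
})

test_that("amputation prunes exactly the non-hip IL muscles and sheds mass", {
  m <- build_reference_model(77.8, 1.81)
  am <- apply_amputation(m)
  il_mus <- Filter(function(x) x$side == "il", am$muscles)
  expect_true(all(vapply(il_mus, function(x)
    identical(x$spanned_joints, "hip_il"), TRUE)))
  expect_setequal(names(il_mus),
                  c("iliopsoas_il", "glutmax_il", "hamstrings_il", "rectfem_il"))
  # no IL muscle spans knee or ankle
  expect_false(any(vapply(am$muscles, function(x)
    x$side == "il" && any(grepl("(knee|ankle)_il", x$spanned_joints)), TRUE)))
  expect_lt(am$mass, m$mass)
  expect_equal(total_mass(am), am$mass, tolerance = 1e-9)
  expect_error(apply_amputation(am), "healthy")
})

test_that("amputee model builder hits the measured total mass", {
  am <- build_amputee_model(68.5, 1.78)
  expect_equal(total_mass(am), 68.5, tolerance = 1e-9)
  expect_equal(am$variant, "amputee")
})

test_that("mirroring restores bilateral symmetry at the healthy mass", {
  am <- build_amputee_model(68.5, 1.78)
  hh <- mirror_to_hypothetical_healthy(am, 72.1)
  expect_equal(total_mass(hh), 72.1, tolerance = 1e-9)
  expect_null(hh$prosthesis)
  for (mus in Filter(function(x) x$side == "il", hh$muscles)) {
    twin <- hh$muscles[[sub("_il$", "_cl", mus$name)]]
    expect_equal(mus$params, twin$params)
    expect_equal(unname(unlist(mus$geometry)), unname(unlist(twin$geometry)))
  }
  # mirroring an already mirrored model is idempotent
  hh2 <- mirror_to_hypothetical_healthy(hh, 72.1)
  expect_equal(hh2$segments, hh$segments)
  expect_equal(names(hh2$muscles), names(hh$muscles))
  expect_warning(mirror_to_hypothetical_healthy(am, 60), "weigh more")
})

test_that("SKG condition sets the knee flexion limit (last call wins)", {
  am <- build_amputee_model(68.5, 1.78)
  m1 <- apply_skg_condition(am, 14.9)
  expect_equal(m1$joints$knee_il$passive$q_upper, deg2rad(14.9))
  m2 <- apply_skg_condition(apply_skg_condition(am, 30), 35)
  expect_equal(m2$joints$knee_il$passive$q_upper, deg2rad(35))
  # the reference limit leaves the model unchanged
  m3 <- apply_skg_condition(am, 137.5)
  expect_equal(m3$joints$knee_il$passive$q_upper,
               am$joints$knee_il$passive$q_upper)
  expect_error(apply_skg_condition(am, 0), "limit_deg")
  expect_error(apply_skg_condition(am, 140), "limit_deg")
})

test_that("orthosis adds mass to the IL thigh/shank and limits flexion", {
  m <- build_reference_model(77.8, 1.81)
  o <- apply_orthosis(m, limit_deg = 20, thigh_mass_add = 0.3,
                      shank_mass_add = 0.3)
  expect_equal(total_mass(o), 78.4, tolerance = 1e-9)
  expect_equal(o$joints$knee_il$passive$q_upper, deg2rad(20))
  o0 <- apply_orthosis(m, limit_deg = 137.5, thigh_mass_add = 0,
                       shank_mass_add = 0)
  expect_equal(total_mass(o0), total_mass(m))
  expect_equal(o0$variant, "healthy")
  expect_error(apply_orthosis(m, 20, -0.1, 0), ">= 0")
})

test_that("muscle moment arms equal minus the length gradient", {
  m <- build_reference_model(77.8, 1.81)
  set.seed(42)
  dofs <- model_dof_names(m)
  for (rep in 1:5) {
    q <- stats::setNames(runif(9, -0.5, 0.5), dofs)
    for (mus in m$muscles[c("hamstrings_il", "gastroc_cl", "vasti_il")]) {
      geo <- muscle_geometry(m, mus$name, q, q * 0)
      for (jn in mus$spanned_joints) {
        h <- 1e-6
        qp <- q; qp[jn] <- qp[jn] + h
        qm <- q; qm[jn] <- qm[jn] - h
        dl <- (muscle_geometry(m, mus$name, qp, q * 0)$l_mt -
                 muscle_geometry(m, mus$name, qm, q * 0)$l_mt) / (2 * h)
        expect_equal(unname(geo$moment_arms[1, jn]), -dl, tolerance = 1e-8)
      }
    }
  }
})
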