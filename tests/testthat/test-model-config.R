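test_that("model construction validates its invariants", {
  m <- poppk_model("m1", 1, list(CL = 0.3, Vc = 3.5),
                   iiv_omega = c(CL = 0.09), sigma_prop = 0.2)
  expect_s3_class(m, "poppk_model")

  m2 <- poppk_model("m2", 2, list(CL = 0.3, Vc = 3.5, Q = 0.1, Vp = 1.5),
                    covariate_effects = list(
                      list(target = "CL", covariate = "wt", form = "power",
                           coefficient = 0.75, reference = 70),
                      list(target = "Vc", covariate = "wt", form = "power",
                           coefficient = 1.0, reference = 70),
                      list(target = "CL", covariate = "ada_positive",
                           form = "binary_multiplier", coefficient = 1.6)),
                    sigma_prop = 0.2)
  expect_equal(m2$n_compartments, 2L)

  # both residual components zero
  expect_error(poppk_model("bad", 1, list(CL = 0.3, Vc = 3.5),
                           sigma_prop = 0, sigma_add = 0),
               "residual error")
  # 1-CMT declaring Q
  expect_error(poppk_model("bad", 1, list(CL = 0.3, Vc = 3.5, Q = 0.1),
                           sigma_prop = 0.2),
               "Q")
  # negative variance
  expect_error(poppk_model("bad", 1, list(CL = 0.3, Vc = 3.5),
                           iiv_omega = c(CL = -0.1), sigma_prop = 0.2),
               "semidefinite")
  # non-positive typical value
  expect_error(poppk_model("bad", 1, list(CL = -0.3, Vc = 3.5),
                           sigma_prop = 0.2),
               "positive")
})

test_that("model files round-trip through serialization", {
  m <- reference_model()
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    serialize_model_spec(m, path)
    back <- load_model_spec(path)
    expect_equal(back$typical, m$typical)
    expect_equal(back$covariate_effects, m$covariate_effects)
    expect_equal(back$random$iiv_omega, m$random$iiv_omega)
    expect_equal(back$random$iov_pi, m$random$iov_pi)
    expect_equal(back$error, m$error)
  }
})

test_that("unknown keys and invalid specs are rejected on load", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(schema_version = 1, name = "x", n_compartments = 1,
                        typical = list(CL = 0.3, Vc = 3.5),
                        sigma_prop = 0.2, bogus_key = 1), path)
  expect_error(load_model_spec(path), "bogus_key")

  path2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(schema_version = 1, name = "x", n_compartments = 1,
                        typical = list(CL = 0.3, Vc = 3.5),
                        sigma_prop = 0, sigma_add = 0), path2)
  expect_error(load_model_spec(path2), "residual error")
})

test_that("structure-only stubs require explicit opt-in", {
  stubs <- list.files(system.file("models", package = "ifxmipd"),
                      pattern = "\\.yaml$", full.names = TRUE)
  expect_gte(length(stubs), 13)        # 12 published structures + reference
  ref <- load_model_spec(file.path(system.file("models", package = "ifxmipd"),
                                   "reference.yaml"))
  expect_s3_class(ref, "poppk_model")
  stub_files <- setdiff(stubs, file.path(system.file("models", package = "ifxmipd"),
                                         "reference.yaml"))
  expect_error(load_model_spec(stub_files[1]), "stub")
  stub <- load_model_spec(stub_files[1], allow_stub = TRUE)
  expect_s3_class(stub, "poppk_model_stub")
})

test_that("dataset compatibility screen reports missing covariates", {
  coh <- small_cohort(5, seed = 2)
  m_ok <- reference_model()
  expect_length(validate_against_dataset(m_ok, coh$data), 0)

  m_fcal <- poppk_model("needs_fcal", 1, list(CL = 0.3, Vc = 3.5),
                        covariate_effects = list(
                          list(target = "CL", covariate = "fcal",
                               form = "exponential", coefficient = 0.001)),
                        sigma_prop = 0.2)
  findings <- validate_against_dataset(m_fcal, coh$data)
  expect_length(findings, 1)
  expect_match(findings, "fcal")

  empty <- event_table(data.frame(id = character(0), time = numeric(0),
                                  evid = integer(0)))
  expect_length(validate_against_dataset(m_ok, empty),
                length(unique(vapply(m_ok$covariate_effects,
                                     function(e) e$covariate, character(1)))))
})
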