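# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fx_phantom <- function() fixture("phantom", function() build_phantom())
fx_aif <- function() fixture("aif", function() input_function())
fx_schedule <- function() fixture("schedule", function() frame_schedule())
fx_basis <- function() fixture("basis", function()
  kinetic_basis(fx_aif(), fx_schedule()))

# small noise-free static study used by evaluation / io / orchestration
# tests (2 noise realizations keep it quick)
fx_st_study <- function() fixture("st_study", function()
  run_study(study_config(motion = "ST", n_realizations = 2, seed = 11)))

# the full motion study under the standard conditions (cardiac +
# respiratory motion, 25 phases, 25 noise realizations); built once and
# shared by the acceptance tests
fx_crm_study <- function() fixture("crm_study", function()
  run_study(study_config(motion = "CRM", n_realizations = 25, seed = 20260926)))
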