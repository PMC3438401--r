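# Shared desk-scale closed-loop fixture (built once per test run): a ~4 x 8 mm
# specimen meshed at 50 um, solved at the elastic increments. Cached because
# several acceptance properties interrogate the same study conditions.

.fixture_cache <- new.env(parent = emptyenv())

acceptance_config <- function() {
  pipeline_config(increments = c(0.03, 0.05), seed = 20260921L)
}

acceptance_prep <- function() {
  if (is.null(.fixture_cache$prep))
    .fixture_cache$prep <- trabevalid:::prepare_specimen(acceptance_config())
  .fixture_cache$prep
}

acceptance_run_tied <- function() {
  if (is.null(.fixture_cache$run_tied))
    .fixture_cache$run_tied <- trabevalid:::run_increments(acceptance_prep(),
                                                           interface_model("tied"))
  .fixture_cache$run_tied
}

acceptance_interface_comparison <- function() {
  if (is.null(.fixture_cache$iface)) {
    .fixture_cache$iface <- compare_interfaces(acceptance_config(),
                                               prep = acceptance_prep(),
                                               tied_run = acceptance_run_tied())
  }
  .fixture_cache$iface
}
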