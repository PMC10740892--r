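# shared fixtures, all generated in code

# small labyrinth used across tests (kept tiny for speed)
tiny_anatomy <- function(n = 6, seed = 42) {
  build_default_labyrinth(n_per_crista = n, seed = seed)
}

# the standard pulse of the stimulation protocol
std_spec <- function(amp_uA = 240, ...) {
  waveform_spec("rect", phase_us = 200, amp_uA = amp_uA, ...)
}

# a straight synthetic fiber at controlled geometry: nodes along +x starting
# at `start_mm`, spacing `spacing_mm`
line_fiber <- function(n_nodes = 15, start_mm = c(0.3, 0, 0),
                       spacing_mm = 0.3, diameter_um = 3) {
  nodes <- cbind(start_mm[1] + spacing_mm * (seq_len(n_nodes) - 1),
                 start_mm[2], start_mm[3])
  tibble::tibble(branch = "LH", fiber = 1L, zone = "central",
                 diameter_um = diameter_um, spacing_mm = spacing_mm,
                 n_nodes = n_nodes, nodes = list(nodes))
}

# hand-built recruitment curve (bypasses simulation)
manual_curve <- function(amp_uA, fractions, branch = "LH",
                         target = "LH") {
  df <- tidyr::expand_grid(amp_uA = amp_uA, branch = branch)
  df$fraction_active <- as.vector(t(fractions))
  tibble::new_tibble(df, class = "vest_recruitment", spec = NULL,
                     stim = paste0(target, "_stim"), target_branch = target)
}

# hand-built eCAP trace
manual_trace <- function(v_uV, dt_ms = 0.002, stim_end_ms = 0) {
  t_ms <- seq_along(v_uV) * dt_ms
  tibble::new_tibble(
    list(t_ms = t_ms, v_rec_uV = v_uV,
         v_ref_uV = rep(NA_real_, length(v_uV)), v_uV = v_uV),
    class = "vest_ecap", filtered = TRUE, stim_end_ms = stim_end_ms,
    fs_hz = 1000 / dt_ms)
}
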