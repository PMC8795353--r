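## shared fixtures: stopping tables are deterministic and moderately
## expensive, build once per test run
tt <- stopping_tables()

## brute-force fixed-step Euler energy-loss integrator (independent oracle
## for the adaptive CSDA propagation)
euler_propagate <- function(E0, stack, tables, step_g_cm2 = 1e-6, floor_mev = 0.05) {
  E <- E0
  for (layer in stack$layers) {
    t_rem <- layer$areal_g_cm2
    while (t_rem > 0) {
      h <- min(t_rem, step_g_cm2)
      E <- E - h * stopping_power(tables, layer$material, E)
      if (E <= floor_mev) return(NA_real_)
      t_rem <- t_rem - h
    }
  }
  E
}

## minimal on-cell spectrum object for closed-form bunch tests
fake_oncell <- function(E_source, E_cell = E_source) {
  structure(list(E_source = E_source, E_cell = E_cell,
                 mean_energy = mean(E_cell),
                 n_sampled = length(E_source), n_out_cup = 0L,
                 n_stopped = 0L, n_on_cell = length(E_source),
                 stack = absorber_stack(material_layer("air", 0)),
                 spectrum = proton_spectrum()),
            class = "on_cell_spectrum")
}

## independent ODR oracle: direct minimisation of the orthogonal objective
## with the latent x profiled out per point by 1D optimisation
odr_oracle <- function(x, sx, y, sy, start) {
  obj <- function(p) {
    f <- function(u) p[1] * exp(-p[2] * u - p[3] * u^2)
    sum(vapply(seq_along(x), function(i) {
      stats::optimize(function(d) ((y[i] - f(x[i] + d)) / sy[i])^2 + (d / sx[i])^2,
                      interval = c(-5 * sx[i], 5 * sx[i]))$objective
    }, 0))
  }
  stats::optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
}
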