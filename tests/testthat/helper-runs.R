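# Shared desk-scale inverse runs for the acceptance tests.  Each benchmark
# is trained once per test session and reused by the criteria that need
# both the recovered parameters and the forward verification.

.accept_cache <- new.env(parent = emptyenv())

acceptance_cylinder <- function() {
  if (is.null(.accept_cache$cyl)) {
    case <- cylinder_case()
    problem <- pinn_cylinder_problem(case, n_pde = 600L, n_data = 600L,
                                     n_boundary = 150L, n_outer = 150L,
                                     seed = 0L)
    est <- train_inverse(problem, train_config(iterations = 20000L,
                                               seeds = 0:1,
                                               log_every = 2000L))
    .accept_cache$cyl <- list(case = case, est = est)
  }
  .accept_cache$cyl
}

acceptance_plate <- function() {
  if (is.null(.accept_cache$plate)) {
    case <- plate_case()
    problem <- pinn_plate_problem(case, n_pde = 500L, n_data = 500L,
                                  seed = 0L)
    est <- train_inverse(problem, train_config(iterations = 6000L,
                                               seeds = 0:1,
                                               log_every = 1000L))
    .accept_cache$plate <- list(case = case, est = est)
  }
  .accept_cache$plate
}

acceptance_cone <- function() {
  if (is.null(.accept_cache$cone)) {
    dom <- truncated_cone_shell(1, 2, 1, 0.1)
    ref <- cone_reference(dom, elastic_params(5, 0.3), 0.01,
                          n_r = 2L, n_theta = 24L, n_z = 10L)
    problem <- pinn_cone_problem(dom, ref$reference, 0.01,
                                 elastic_params(5, 0.3),
                                 n_pde = 600L, seed = 0L)
    est <- train_inverse(problem, train_config(iterations = 12000L,
                                               seeds = 0L,
                                               decay_rate = 0.66,
                                               decay_interval = 5000L,
                                               freeze_material = 3600L,
                                               log_every = 1000L))
    .accept_cache$cone <- list(ref = ref, est = est)
  }
  .accept_cache$cone
}

acceptance_membrane <- function() {
  if (is.null(.accept_cache$membrane)) {
    dom <- truncated_cone_shell(10, 20, 10, 1)
    ref <- membrane_reference(dom, elastic_params(0.52684, 0.317),
                              pressure = 0.0129, rho = 1e-3, t_end = 2,
                              nsteps = 10L, n_r = 1L, n_theta = 12L,
                              n_z = 4L)
    problem <- pinn_membrane_problem(dom, ref$reference, "neo-hookean",
                                     pressure = 0.0129, rho = 1e-3,
                                     t_end = 2,
                                     truth = c(E = 0.52684, nu = 0.317),
                                     n_pde = 800L, seed = 0L)
    est <- train_inverse(problem, train_config(iterations = 8000L,
                                               seeds = 0L,
                                               decay_rate = 0.45,
                                               decay_interval = 15000L,
                                               freeze_material = 2400L,
                                               log_every = 1000L))
    .accept_cache$membrane <- list(ref = ref, est = est)
  }
  .accept_cache$membrane
}
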