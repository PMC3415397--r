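# Shared fixtures, built in code and cached for the test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

decay_model <- function() {
  fixture("decay", function()
    model_definition("decay", "V", list(V = "-V")))
}

# single-regime leaky integrate-and-fire with a terminal threshold event
lif_model <- function(drive = 2, tol_t = 1e-10) {
  model_definition("lif", "V", list(V = "(-V + drive)/tau"),
                   params = c(tau = 10, drive = drive, Vth = 1),
                   events = list(event_definition("spike", "V - Vth",
                                                  direction = 1,
                                                  terminal = TRUE,
                                                  tol_t = tol_t)))
}

lif_selfreset <- function() {
  fixture("lif_selfreset", function() {
    hybrid_model(
      regimes = list(regime("fire", lif_model())),
      transitions = list(transition("fire", "spike", "fire",
                                    reset = list(V = "0"))),
      state_names = "V", initial = "fire")
  })
}

hh_fix <- function(I = 10) {
  fixture(paste0("hh_", I), function() make_hh_model("hh1952", I_app = I))
}

hh_run <- function(I = 10, t_end = 120) {
  fixture(paste0("hhrun_", I, "_", t_end), function() {
    hh <- hh_fix(I)
    integrate_ode(hh$model, hh_initial_state(hh), c(0, t_end))
  })
}

# full 300 ms run + gamma = 3 epochs/template (the standard analysis
# protocol), shared between dssrt unit tests and the acceptance suite
hh_analysis <- function(I = 10, gamma = 3) {
  fixture(paste0("hhan_", I, "_", gamma), function() {
    derive_hh_template("hh1952", I_app = I, gamma = gamma)
  })
}

# random states over the HH state space (V in mV, gating in (0, 1))
random_hh_states <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(V = stats::runif(n, -95, 45),
             m = stats::runif(n, 0.02, 0.98),
             h = stats::runif(n, 0.02, 0.98),
             n = stats::runif(n, 0.02, 0.98))
}

# random smooth expression trees over symbols `syms`, safe to evaluate and
# differentiate for bindings in [0.3, 1.7]
random_expr <- function(depth, syms, r) {
  leaf <- function() {
    if (r() < 0.5) as.symbol(sample(syms, 1))
    else round(stats::runif(1, 0.5, 2), 3)
  }
  if (depth <= 0 || r() < 0.25) return(leaf())
  op <- sample(c("+", "-", "*", "/", "pow2", "exp", "sin", "cos",
                 "tanh", "sqrt1"), 1)
  a <- random_expr(depth - 1L, syms, r)
  b <- random_expr(depth - 1L, syms, r)
  switch(op,
         "+" = call("+", a, b),
         "-" = call("-", a, b),
         "*" = call("*", a, b),
         "/" = call("/", a, call("+", call("^", b, 2), 1)),
         pow2 = call("^", call("+", call("^", a, 2), 0.5),
                     round(stats::runif(1, 1, 3), 1)),
         exp = call("exp", call("*", 0.4, a)),
         sin = call("sin", a),
         cos = call("cos", a),
         tanh = call("tanh", a),
         sqrt1 = call("sqrt", call("+", call("^", a, 2), 1)))
}

make_rng <- function(seed) {
  set.seed(seed)
  function() stats::runif(1)
}
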