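# Shared fixtures: small deterministic objects built in code.

toy_segment <- function(n = 200, amp = 1, seed = 1, task = "Coagulation",
                        skill = "Expert") {
  with_seed_local(seed, {
    tr <- synth_task_waveform(task, n, amp)
    forcepsml:::new_force_segment(tr, task, skill, "S01")
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

random_segment <- function(n = NULL, seed = 1) {
  with_seed_local(seed, {
    n <- n %||% sample(40:400, 1)
    left <- abs(stats::rnorm(n, 1, 0.4))
    right <- left + stats::rnorm(n, 0, 0.1)
    forcepsml:::new_force_segment(cbind(left, pmax(right, 0)),
                                  sample(forcepsml:::TASKS, 1),
                                  sample(c("Expert", "Novice"), 1), "S01")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# toy plateau dataset: point-wise ON where amplitude is high
toy_plateau_windows <- function(n, L = 32, seed = 7) {
  with_seed_local(seed, {
    x <- array(0, c(n, L, 2))
    y <- matrix(0L, n, L)
    for (i in seq_len(n)) {
      s <- sample(4:(L / 3), 1)
      w <- sample((L / 4):(L / 2), 1)
      y[i, s:(s + w - 1)] <- 1L
      base <- as.numeric(y[i, ]) * 2
      x[i, , 1] <- base + stats::rnorm(L, 0, 0.1)
      x[i, , 2] <- base + stats::rnorm(L, 0, 0.1)
    }
    list(x = x, y = y)
  })
}

# toy two-class window set separable by amplitude
toy_class_windows <- function(n, L = 64, seed = 2) {
  with_seed_local(seed, {
    x <- array(0, c(n, L, 2))
    lab <- sample(c("lo", "hi"), n, TRUE)
    for (i in seq_len(n)) {
      a <- if (lab[i] == "hi") 2 else 0.5
      x[i, , 1] <- a * sin(seq(0, 4 * pi, length.out = L)) +
        stats::rnorm(L, 0, 0.2)
      x[i, , 2] <- x[i, , 1] + stats::rnorm(L, 0, 0.1)
    }
    list(x = x, lab = lab)
  })
}
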