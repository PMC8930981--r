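# Independent brute-force equilibrium oracle. Deliberately shares no code
# with the package solver: the gape rotation is built as an axis-angle
# rotation MATRIX (not per-point Rodrigues vectors) and the unknowns
# (bite magnitude + joint force vector) come from one 4x4 linear solve of
# the force balance plus the hinge-axis moment balance. Residual moments
# about two independent axes through the joint center are returned so a
# test can confirm they are pure hinge reaction moments (perpendicular to
# the axis), i.e. that the axis-moment balance itself is satisfied.
oracle_solve <- function(model, label, gape_deg, orientation_deg = 0,
                         stress = 30) {
  jl <- model$joint_left; jr <- model$joint_right
  ctr <- (jl + jr) / 2
  ax <- (jl - jr) / sqrt(sum((jl - jr)^2))
  K <- matrix(c(0, -ax[3], ax[2],
                ax[3], 0, -ax[1],
                -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  rotmat <- function(theta) diag(3) + sin(theta) * K +
    (1 - cos(theta)) * (K %*% K)

  # opening sense: the most anterior bite point must move ventrally
  bp0 <- as.matrix(model$bite_points[, c("x", "y", "z")])
  ref <- bp0[which.max(bp0[, 1L]), ]
  probe <- drop(rotmat(pi / 180) %*% (ref - ctr)) + ctr
  sgn <- if (probe[3L] < ref[3L]) 1 else -1
  R <- rotmat(sgn * (gape_deg - model$gape_reference_deg) * pi / 180)
  rot <- function(p) drop(R %*% (p - ctr)) + ctr

  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  mu <- model$muscles
  Fsum <- c(0, 0, 0); Tsum <- c(0, 0, 0)
  for (i in seq_len(nrow(mu))) {
    ins <- rot(c(mu$insertion_x[i], mu$insertion_y[i], mu$insertion_z[i]))
    ori <- c(mu$origin_x[i], mu$origin_y[i], mu$origin_z[i])
    d <- ori - ins; d <- d / sqrt(sum(d^2))
    f <- mu$acsa[i] * stress * d
    Fsum <- Fsum + f
    Tsum <- Tsum + cr(ins - ctr, f)
  }

  up <- c(0, 0, 1)
  upp <- up - sum(up * ax) * ax
  base <- upp / sqrt(sum(upp^2))
  a <- orientation_deg * pi / 180
  u <- base * cos(a) + cr(ax, base) * sin(a)

  bp <- rot(as.numeric(model$bite_points[model$bite_points$label == label,
                                         c("x", "y", "z")]))
  arm_vec <- cr(bp - ctr, u)

  # unknowns x = (F_bite, Jx, Jy, Jz):
  #   Fsum - F u + J = 0            (force balance; reaction on jaw = -F u)
  #   Tsum . ax - F (arm_vec . ax) = 0   (moment balance about hinge axis)
  A <- rbind(cbind(-u, diag(3)),
             c(-sum(arm_vec * ax), 0, 0, 0))
  b <- c(-Fsum, -sum(Tsum * ax))
  sol <- solve(A, b)
  Fb <- sol[1L]; J <- sol[2:4]
  # total torque about the joint center with the solved forces
  Ttot <- Tsum + cr(bp - ctr, -Fb * u)
  list(bite_force = Fb, joint_force = J,
       axis_moment_residual = sum(Ttot * ax),
       perp_moment = Ttot - sum(Ttot * ax) * ax)
}
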