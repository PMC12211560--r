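#!/usr/bin/env Rscript
# Time-resolved cristae retraction with conserved IMM length.
#
# Emulates long STED recordings in which cristae progressively retract into
# the boundary membrane and the mitochondrion rounds up into a sphere,
# without gaining or losing membrane: the total 2D IMM length
# P + 2*sum(l) is constant across frames, so every nm of retracted crista
# reappears in the boundary.

library(mitoshape)

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

frames <- generate_timeseries(seq(1, 0, length.out = 10),
                              axis_length = 500, radius = 125, dt = 15)
write_traces(frames, "results/timeseries_traces.json")

prof <- timeseries_profile(frames)
write.csv(prof$profile, "results/timeseries_profile.csv", row.names = FALSE)

message(sprintf("circularity %.3f -> %.3f; [cristae/IMM]%% %.1f -> %.1f; Kendall tau = %.2f",
                prof$profile$circularity[1],
                prof$profile$circularity[nrow(prof$profile)],
                prof$profile$cristae_frac_2d[1],
                prof$profile$cristae_frac_2d[nrow(prof$profile)],
                prof$kendall_tau))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(prof$profile, aes(time)) +
    geom_line(aes(y = cristae_frac_2d, colour = "[cristae/IMM]%")) +
    geom_point(aes(y = cristae_frac_2d, colour = "[cristae/IMM]%")) +
    geom_line(aes(y = circularity * 50, colour = "circularity")) +
    geom_point(aes(y = circularity * 50, colour = "circularity")) +
    scale_y_continuous("[cristae/IMM]%",
                       sec.axis = sec_axis(~ . / 50, name = "circularity")) +
    labs(x = "time (s)", colour = NULL) +
    theme_minimal()
  ggsave("results/figures/05_timeseries.pdf", p, width = 5.5, height = 4)
}
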