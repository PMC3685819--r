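# shared fixtures: the default study conditions
SOLUTES <- default_solutes()
IFACE <- interface_spec()

# geometry fixtures matched to the measured wall-level diffusion
CHANNEL_MATCHED <- channel_geometry(6.4, channels_per_pd = 9)
SLIT_MATCHED <- slit_geometry(5.2)
HYDROGEL_MATCHED <- hydrogel_geometry(0.49, fiber_radius = 15)

# evaluate effective_diffusion quietly (literal mode emits a one-time note)
deff_quiet <- function(...) suppressMessages(effective_diffusion(...))
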