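# Annotated fawspread run configuration (schema version 1).
# Unknown keys are rejected; every key below except `climate` and
# `simulation.init` is optional and shown with its default.
version: 1
output_dir: fawspread-output
verbosity: 1          # 0 = silent, 1 = summary tables

climate:
  # Either a NetCDF file with SMAP-like fields...
  # path: climate.nc
  # ...or a built-in synthetic preset:
  preset: tropics_to_temperate
  rows: 40
  cols: 20
  start: 2019-01-01
  end: 2019-12-31
  seed: 1

thermal:
  r_ref: 0.16         # intrinsic rate of increase at 27 degC (1/day);
                      # published range 0.12-0.20

stress:               # critical thresholds and mortality rates
  CTmin: 12.97        # degC
  mTmin: 0.2          # 1/(degC day)
  CTmax: 39.8         # degC
  mTmax: 0.02         # 1/(degC day)
  Cwilting: 0.5       # fraction
  mwilting: 0.2       # 1/day per unit exceedance

kernel:               # short-range dispersal
  alpha: 0.01         # cells; 2*alpha = mean displacement of the kernel
  dS: 2               # truncation distance (cells)
  p_disperse: 0.01    # fraction leaving per weekly step

jumps:                # long-range dispersal
  beta: 0.05          # proportion jumping per weekly step
  radius_km: 540      # maximum jump distance

population:
  K: 1.0e9            # carrying capacity per cell (individuals)
  theta: 10000        # Allee extinction threshold per cell

simulation:
  start: 2019-01-01
  end: 2019-12-31
  replicates: 2
  seed: 1
  snapshot_every: 4   # store a population snapshot every 4 weeks
  init:               # founder populations (row 1 = northernmost)
    - {row: 2, col: 10, abundance: 1.0e6}
  regions:            # optional reporting regions (default: whole grid)
    - {region: north, row: 2, col: 10}
    - {region: north, row: 3, col: 10}
    - {region: south, row: 39, col: 10}
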