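# Cultivar parameter set: Koshihikari-like temperate japonica.
# SYNTHETIC calibration, version 1: values were chosen to give realistic
# Japanese lowland behaviour under the package's weather generator
# (heading late July to early August from May 01 planting, maturity in
# early September, grain yields around 5-7 t/ha, maximum harvest index
# 0.4), not fitted to field observations. Units noted per key.
#
# Phenology, vegetative phase (days to heading, temperature response)
Gv: 55            # d, minimum days to heading under optimal conditions
A: 0.15           # 1/C, temperature response slope
Th: 18            # C, temperature at half the maximum developmental rate
DVI_star: 0.45    # -, developmental index at photoperiod-sensitivity onset
Lc: 16.5          # h, critical day length
Bp: 1.2           # 1/h, photoperiod response constant
# Phenology, grain filling
Gr: 30            # d, minimum grain-filling duration
Kr: 0.18          # 1/C
Tcr: 10           # C, base temperature for grain filling
# Radiation conversion and CO2 response
C0: 1.6           # g DM / MJ absorbed global radiation, at 330 ppm CO2
Rm: 0.4           # -, asymptotic relative CO2 response
Kc: 200           # ppm, CO2 half-saturation offset
Cf: 1.6           # g DM / MJ, grain-filling decline numerator constant
Bf: 0.003         # -, grain-filling decline shape
tf: 0.15          # -, grain-filling decline time constant (in DVI units)
# Harvest index and sterility
hm: 0.4           # -, maximum harvest index
Kh: 4             # -, harvest-index maturity response
gamma0: 0.046     # fraction, baseline spikelet sterility
Kq: 0.0017        # fraction per (C d)^aq, cooling response coefficient
aq: 1.56          # -, cooling response exponent
# Canopy surrogate (leaf area and light interception)
LAI_max: 4.5      # m2/m2, peak leaf area index, reached at DVI = 1
k_beer: 0.6       # -, canopy extinction coefficient
LAI_rise: 1.8     # -, rise-phase shape exponent (LAI ~ DVI^LAI_rise)
LAI_end_frac: 0.3 # -, fraction of peak LAI remaining at maturity
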