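# Frozen base-fold internal coordinates (C-alpha virtual bond angles and
# torsions, degrees) for reference IDs 40-300. Derived once from an
# explicit self-avoiding serpentine layout of helical zigzag rods joined
# by solved turn bridges; reproduced at build time by .build_ca_segment.
.FOLD_THETA <- c( 0, 0, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 135.7761987, 60.85551107,
  61.78575752, 60.11276597, 63.05370243, 60.62786417, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 95.76704018, 118.4298418, 128.0961827, 96.43008865,
  125.2220825, 103.3820301, 89.56472896, 89.56472896, 89.56472896,
  89.56472896, 89.56472896, 89.56472896, 89.56472896, 89.56472896,
  89.56472896, 89.56472896, 89.56472896, 89.56472896, 89.56472896,
  89.56472896, 89.56472896, 89.56472896, 89.56472896, 89.56472896,
  89.56472896, 89.56472896, 89.56472896, 89.56472896, 89.56472896,
  89.56472896, 89.56472896, 89.56472896, 112.0623224, 130.9317209,
  127.0343796, 134.4641827, 128.183104, 164.9447739, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 113.266532, 106.2808017, 99.26323311, 66.02764403,
  126.4840316, 75.58126804, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  135.1148425, 73.44890752, 102.7044251, 65.34875468, 73.44526239,
  116.5120313, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 115, 115, 115, 115, 115, 115, 115, 115, 115,
  115, 115, 115, 115, 115, 115, 115, 115, 115, 115, 115, 115, 115, 115,
  115, 115, 115, 63.32796465, 145.9376905, 92.731477, 106.4794889,
  134.9262888, 60.73661512, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 75.43860624, 68.65358065,
  136.5072676, 60.03691705, 93.69463925, 60.02911982, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 75.43866346, 68.65351274,
  136.5073413, 60.03698026, 93.69457059, 60.02906052, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895, 143.2226895, 143.2226895,
  143.2226895, 143.2226895, 143.2226895)
.FOLD_TAU <- c( 0, 0, 0, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180,
  180, 180, 180, 180, 180, 180, -94.24686322, 9.660280885, -173.1931286,
  150.6806514, 142.3050795, -158.0235846, 115.42604, 180, 180, 180, 180,
  180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180,
  180, 180, 180, -72.10394633, 107.2803104, -0.004052056529, 0.01029169613,
  -179.9981417, 46.1715856, 76.44286389, 180, 180, 180, 180, 180, 180, 180,
  180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180,
  180, 180, 180, 180, 180, 180, 0, 0, 0, 180, 180, 180, 180, 180, 180, 180,
  180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180,
  180, 180, -37.53960348, -81.85905462, -177.9901165, -157.9998312,
  -13.134954, 109.3332889, 168.162291, 180, 180, 180, 180, 180, 180, 180,
  180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 75.09964228,
  59.46093179, 175.1568453, 57.40629541, 119.4297132, -120.1192265,
  -62.20038908, 180, 180, 180, 180, 180, 20, 20, 20, 20, 20, 20, 20, 20,
  20, 20, 20, 20, 20, 20, 20, 20, 20, 20, 20, 20, 20, 20, 20, 20, 20, 20,
  -169.5827103, -115.4314849, -98.23491385, 106.1578061, -175.9139293,
  -68.09286113, 7.601683687, 180, 180, 180, 180, 180, 180, 180, 180, 180,
  180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180,
  180, 180, -172.2896726, 74.25401429, 22.79804623, -170.5547553,
  -116.0273006, -116.0680908, -80.20864762, 180, 180, 180, 180, 180, 180,
  180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180,
  180, 180, 180, 172.2896617, -74.25390208, -22.79838537, 170.5550923,
  116.0273553, 116.0681434, 80.20865625, 180, 180, 180, 180, 180, 180, 180,
  180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180, 180,
  180, 180)
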