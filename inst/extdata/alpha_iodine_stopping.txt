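# Alpha-particle total mass stopping power in elemental iodine
# ICRU-49-style evaluation: proton Bethe stopping power (I = 491 eV) at
# equal velocity, scaled by the Barkas effective-charge factor for helium
# (coefficient 191.2489) and a global normalisation (0.9697); power-law peak
# roll-off below the Bethe validity limit.  The water table is calibrated
# to published CSDA anchors for the 211At alpha lines:
# R(5.867 MeV) = 48 um, R(7.450 MeV) = 70 um in unit-density water.
# columns: energy_MeV  mass_stopping_power_MeV_cm2_per_g
1.000000e-03 1.117007e+01
1.068506e-03 1.150815e+01
1.141705e-03 1.185646e+01
1.219919e-03 1.221532e+01
1.303491e-03 1.258503e+01
1.392788e-03 1.296594e+01
1.488202e-03 1.335838e+01
1.590153e-03 1.376269e+01
1.699088e-03 1.417924e+01
1.815486e-03 1.460840e+01
1.939857e-03 1.505055e+01
2.072749e-03 1.550608e+01
2.214745e-03 1.597539e+01
2.366468e-03 1.645891e+01
2.528586e-03 1.695707e+01
2.701809e-03 1.747030e+01
2.886899e-03 1.799907e+01
3.084669e-03 1.854384e+01
3.295988e-03 1.910510e+01
3.521783e-03 1.968335e+01
3.763046e-03 2.027910e+01
4.020838e-03 2.089288e+01
4.296289e-03 2.152524e+01
4.590611e-03 2.217673e+01
4.905096e-03 2.284795e+01
5.241124e-03 2.353948e+01
5.600173e-03 2.425194e+01
5.983819e-03 2.498597e+01
6.393746e-03 2.574221e+01
6.831756e-03 2.652134e+01
7.299773e-03 2.732405e+01
7.799851e-03 2.815106e+01
8.334188e-03 2.900309e+01
8.905130e-03 2.988092e+01
9.515186e-03 3.078532e+01
1.016703e-02 3.171708e+01
1.086354e-02 3.267705e+01
1.160775e-02 3.366608e+01
1.240296e-02 3.468504e+01
1.325263e-02 3.573484e+01
1.416052e-02 3.681641e+01
1.513060e-02 3.793072e+01
1.616714e-02 3.907876e+01
1.727468e-02 4.026154e+01
1.845810e-02 4.148012e+01
1.972259e-02 4.273559e+01
2.107371e-02 4.402905e+01
2.251739e-02 4.536166e+01
2.405996e-02 4.673461e+01
2.570822e-02 4.814911e+01
2.746938e-02 4.960642e+01
2.935120e-02 5.110784e+01
3.136194e-02 5.265470e+01
3.351042e-02 5.424838e+01
3.580608e-02 5.589030e+01
3.825902e-02 5.758191e+01
4.087999e-02 5.932472e+01
4.368052e-02 6.112028e+01
4.667290e-02 6.297019e+01
4.987027e-02 6.487608e+01
5.328669e-02 6.683967e+01
5.693714e-02 6.886268e+01
6.083768e-02 7.094692e+01
6.500543e-02 7.309425e+01
6.945869e-02 7.530656e+01
7.421703e-02 7.758584e+01
7.930135e-02 7.993410e+01
8.473397e-02 8.235344e+01
9.053876e-02 8.484600e+01
9.674121e-02 8.741401e+01
1.033686e-01 9.005974e+01
1.104499e-01 9.278554e+01
1.180164e-01 9.559385e+01
1.261013e-01 9.848716e+01
1.347400e-01 1.014680e+02
1.439705e-01 1.045391e+02
1.538333e-01 1.077032e+02
1.643718e-01 1.109630e+02
1.756323e-01 1.143215e+02
1.876641e-01 1.177816e+02
2.005203e-01 1.213464e+02
2.142571e-01 1.250192e+02
2.289350e-01 1.288031e+02
2.446184e-01 1.327016e+02
2.613763e-01 1.367180e+02
2.792821e-01 1.408560e+02
2.984147e-01 1.451192e+02
3.188579e-01 1.495115e+02
3.407015e-01 1.540367e+02
3.640417e-01 1.586989e+02
3.889807e-01 1.635022e+02
4.156282e-01 1.684508e+02
4.441013e-01 1.735493e+02
4.745249e-01 1.788020e+02
5.070327e-01 1.842137e+02
5.417675e-01 1.897893e+02
5.788818e-01 1.955336e+02
6.185387e-01 2.014517e+02
6.609124e-01 2.075490e+02
7.061889e-01 2.138308e+02
7.545671e-01 2.203027e+02
8.062595e-01 2.269706e+02
8.614931e-01 2.338402e+02
9.205106e-01 2.409178e+02
9.835711e-01 2.482095e+02
1.050952e+00 2.557220e+02
1.122948e+00 2.634618e+02
1.199877e+00 2.714359e+02
1.282076e+00 2.796514e+02
1.369906e+00 2.881155e+02
1.463752e+00 2.968358e+02
1.564028e+00 3.058200e+02
1.671174e+00 3.150762e+02
1.785659e+00 3.246125e+02
1.907988e+00 3.344374e+02
2.038696e+00 3.445597e+02
2.178359e+00 3.549884e+02
2.327590e+00 3.657327e+02
2.487044e+00 3.715195e+02
2.657421e+00 3.715448e+02
2.839471e+00 3.700499e+02
3.033992e+00 3.672167e+02
3.241838e+00 3.632139e+02
3.463924e+00 3.581969e+02
3.701224e+00 3.523082e+02
3.954780e+00 3.456784e+02
4.225706e+00 3.384264e+02
4.515192e+00 3.306598e+02
4.824510e+00 3.224758e+02
5.155018e+00 3.139621e+02
5.508168e+00 3.051967e+02
5.885511e+00 2.962495e+02
6.288704e+00 2.871823e+02
6.719518e+00 2.780496e+02
7.179846e+00 2.688996e+02
7.671708e+00 2.597739e+02
8.197267e+00 2.507091e+02
8.758829e+00 2.417366e+02
9.358862e+00 2.328832e+02
1.000000e+01 2.241718e+02
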