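# PLUMED input generated by slowcv
# units: nm, kJ/mol, ps, rad

t_chi1_TRP41: TORSION ATOMS=5,7,9,11
t_chi2_TYR77: TORSION ATOMS=21,23,25,27

sin_chi1_TRP41: MATHEVAL ARG=t_chi1_TRP41 FUNC=sin(x) PERIODIC=NO
cos_chi1_TRP41: MATHEVAL ARG=t_chi1_TRP41 FUNC=cos(x) PERIODIC=NO
sin_chi2_TYR77: MATHEVAL ARG=t_chi2_TYR77 FUNC=sin(x) PERIODIC=NO
cos_chi2_TYR77: MATHEVAL ARG=t_chi2_TYR77 FUNC=cos(x) PERIODIC=NO

SF1: MATHEVAL ARG=sin_chi1_TRP41,cos_chi1_TRP41,sin_chi2_TYR77,cos_chi2_TYR77 VAR=v1,v2,v3,v4 FUNC=0.75*v1-0.5*v2+0.25*v3+0.0625*v4-0.125 PERIODIC=NO

metad: METAD ARG=SF1 SIGMA=0.32 HEIGHT=1.5 PACE=500 BIASFACTOR=20 TEMP=300 FILE=HILLS

PRINT ARG=SF1,metad.bias STRIDE=500 FILE=COLVAR
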