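label,dx,dy,dz
Nz,0,1,-0.30
AL,-1,0,-0.30
AR,1,0,-0.30
Cz,0,0,1
Pz,0,-0.70,0.90
Iz,0,-1,-0.05
FRONT,0,1,0.45
LEFT,-1,0,0.25
RIGHT,1,0,0.25
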