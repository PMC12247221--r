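pattern,field,value
qtof,mass_analyzer,TOF
q-tof,mass_analyzer,TOF
tof,mass_analyzer,TOF
orbitrap,mass_analyzer,Orbitrap
q-?exactive,mass_analyzer,Orbitrap
q-?exactive,manufacturer,Thermo
exactive,mass_analyzer,Orbitrap
exactive,manufacturer,Thermo
lumos,mass_analyzer,Orbitrap
lumos,manufacturer,Thermo
velos,mass_analyzer,Orbitrap
velos,manufacturer,Thermo
fusion,mass_analyzer,Orbitrap
fusion,manufacturer,Thermo
ft-?icr,mass_analyzer,FTICR
ion ?trap,mass_analyzer,IonTrap
lcq,mass_analyzer,IonTrap
lcq,manufacturer,Thermo
ltq,mass_analyzer,IonTrap
ltq,manufacturer,Thermo
qqq,mass_analyzer,QQQ
triple ?quad(rupole)?,mass_analyzer,QQQ
impact,mass_analyzer,TOF
impact,manufacturer,Bruker
maxis,mass_analyzer,TOF
maxis,manufacturer,Bruker
esi,ionization_method,ESI
nanoesi,ionization_method,ESI
electrospray,ionization_method,ESI
apci,ionization_method,APCI
appi,ionization_method,APPI
maldi,ionization_method,MALDI
cid,dissociation_method,CID
hcd,dissociation_method,HCD
etd,dissociation_method,ETD
thermo,manufacturer,Thermo
bruker,manufacturer,Bruker
agilent,manufacturer,Agilent
waters,manufacturer,Waters
sciex,manufacturer,Sciex
shimadzu,manufacturer,Shimadzu
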