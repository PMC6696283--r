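id,method,rt_s,mz,formula,transformation_label,intensity_class,parent_formula,isomer_annotation
MON A,Std,162,693.4184,C36H62O11Na,,s,,
MON B,Std,120,679.4028,C35H60O11Na,,w,,
TP 1,EC-GC,92,619.3817,C33H56O9Na,-CO2 -2x CH2,w,C35H60O11,
TP 2,EC-GC,102,665.4235,C35H62O10Na,-CO2 -2H +H2O,w,C36H62O11,
TP 3,EC-GC/RLM,109,633.3973,C34H58O9Na,-CO2 -CH2,s,C36H62O11,
TP 4,EC-GC,132,647.4130,C35H60O9Na,-CO2 -2H,ms,C36H62O11,
TP 5,EC-GC,133,679.4392,C36H64O10Na,-CO2 -2H +OCH3 +H,s,C36H62O11,stereoisomer
TP 6,EC-GC,144,679.4392,C36H64O10Na,-CO2 -2H +OCH3 +H,ms,C36H62O11,stereoisomer
TP 7,EC-MD,107,707.4341,C37H64O11Na,+CH2,vw,C36H62O11,
TP 8,RLM,79,665.3877,C34H58O11Na,-2 CH2,vw,C35H60O11,
TP 9,RLM,95,679.4028,C35H60O11Na,-CH2,w,C36H62O11,
TP 10,Hyd,75,693.4184,C36H62O11Na,diastereomer,s,C36H62O11,diastereomer
TP 11,Hyd,99,693.4184,C36H62O11Na,ring cleavage,ms,C36H62O11,ring-opened
TP 12,Hyd,86,675.4079,C36H60O10Na,-H2O,s,C36H62O11,
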