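method,category,label,amount,labour_hours
camera,gear,Gear,5014,NA
camera,labour,Labour gear preparation,5900,40
camera,labour,Labour field servicing,3471,30
camera,labour,Labour photogrammetry programming,2647,2
camera,labour,Labour video perusing,12247,418
camera,expendables,"Expendables (batteries, hard drives, SD cards)",1206,NA
field,gear,Gear,10359,NA
field,labour,Labour,36280,588
field,expendables,Expendables,941,NA
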