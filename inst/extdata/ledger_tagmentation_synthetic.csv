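section,name,assay,stage,unit_price_eur,units_per_case,is_flowcell,tariff_label,annual_cost_eur,annual_working_minutes,hands_on_minutes_per_case,allocation,base_fte,fte_increment,redundancy_fte_low,redundancy_fte_high,cases_per_fte,purchase_price_eur,operating_years,annual_maintenance_eur,backup_units,is_sequencing_platform,key,value
consumables,NovaSeq X 25B flow cell (300 cycles),WGS,sequencing,16480,0.125,TRUE,,,,,,,,,,,,,,,,,
consumables,WGS sequencing run consumables & QC,WGS,sequencing,8.48,1,FALSE,,,,,,,,,,,,,,,,,
consumables,WGS library prep kit (tagmentation),WGS,library_prep,98.75,1,FALSE,,,,,,,,,,,,,,,,,
consumables,"WGS library QC (fluorometry, capillary electrophoresis)",WGS,library_prep,13.44,1,FALSE,,,,,,,,,,,,,,,,,
consumables,DNA/RNA extraction (FFPE + blood reference),WTS,extraction,48.9,1,FALSE,,,,,,,,,,,,,,,,,
consumables,WTS library prep kit,WTS,library_prep,162.71,1,FALSE,,,,,,,,,,,,,,,,,
consumables,WTS sequencing reagent share,WTS,sequencing,67.25,1,FALSE,,,,,,,,,,,,,,,,,
personnel,Technical assistant (wet lab),,,,,,TV-L E8/3,60568.5,107400,275.78,hands_on,0,1,1,1,,,,,,,,
personnel,Biologist (variant interpretation),,,,,,TV-L E13/3,82866,107400,79.26,hands_on,0,0.5,0.5,1,,,,,,,,
personnel,Trainee doctor (tumour annotation),,,,,,TV-Ä Ä1/3,95709.5,107400,7.5,hands_on,0,0.5,0,0,,,,,,,,
personnel,Medical specialist (report sign-out),,,,,,TV-Ä Ä2/3,130000,107400,4.432,hands_on,0,0.5,0,0,,,,,,,,
personnel,Bioinformatician (pipeline development),,,,,,TV-L E13/3,82866,107400,,annual_fte,0.5,0.5,0,0,,,,,,,,
personnel,Bioinformatician (database maintenance),,,,,,TV-L E13/3,82866,107400,,annual_fte,0.5,0.5,0,0,,,,,,,,
personnel,Quality management,,,,,,TV-L E13/3,82866,107400,,annual_fte,0.5,0.5,0,0,,,,,,,,
personnel,Case management,,,,,,TV-L E8/3,60568.5,107400,,annual_fte,0.5,0.5,0,0,2000,,,,,,,
equipment,NovaSeq X Plus sequencing platform,,,,,,,,,,,,,,,,1100000,5,90000,1,TRUE,,
equipment,DRAGEN compute server,,,,,,,,,,,,,,,,250000,5,25000,1,FALSE,,
equipment,Storage servers (raw + processed data),,,,,,,,,,,,,,,,140000,7,6000,1,FALSE,,
equipment,Extraction & library-prep instruments,,,,,,,,,,,,,,,,94500,7,1523,1,FALSE,,
equipment,Loaner instrument service retainer,,,,,,,,,,,,,,,,0,7,437,2,FALSE,,
data_costs,,,,,,,,,,,,,,,,,,,,,,per_gigabase_eur,0.2
data_costs,,,,,,,,,,,,,,,,,,,,,,per_case_licence_eur,69.22
data_costs,,,,,,,,,,,,,,,,,,,,,,per_case_storage_eur,167.84
rd,,,,,,,,,,,,,,,,,,,,,,rd_annual_eur,41433
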