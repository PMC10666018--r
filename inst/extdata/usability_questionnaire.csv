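"participant_id","item_id","domain","question","score"
"P1","ease_hw_instructions","ease_of_use","Are the instructions on the hardware configuration clear to follow?",4
"P1","ease_hw_setup","ease_of_use","Is the hardware configuration easy in practice?",4
"P1","ease_use_instructions","ease_of_use","Are the instructions on use clear and easy to follow?",4
"P1","ease_interface","ease_of_use","Is the user interface pleasant?",4
"P1","playability","playability","Is the exergame easy to be played?",5
"P1","enjoyment_trainer","enjoyment","Does a virtual trainer increase the enjoyment towards exercise?",4
"P1","satisfaction","satisfaction","Are you satisfied of the experience with the exergame?",3
"P1","acceptance_home","acceptance","Are you motivated to use the exergame autonomously at home?",3
"P2","ease_hw_instructions","ease_of_use","Are the instructions on the hardware configuration clear to follow?",4
"P2","ease_hw_setup","ease_of_use","Is the hardware configuration easy in practice?",4
"P2","ease_use_instructions","ease_of_use","Are the instructions on use clear and easy to follow?",4
"P2","ease_interface","ease_of_use","Is the user interface pleasant?",4
"P2","playability","playability","Is the exergame easy to be played?",4
"P2","enjoyment_trainer","enjoyment","Does a virtual trainer increase the enjoyment towards exercise?",4
"P2","satisfaction","satisfaction","Are you satisfied of the experience with the exergame?",4
"P2","acceptance_home","acceptance","Are you motivated to use the exergame autonomously at home?",3
"P3","ease_hw_instructions","ease_of_use","Are the instructions on the hardware configuration clear to follow?",3
"P3","ease_hw_setup","ease_of_use","Is the hardware configuration easy in practice?",4
"P3","ease_use_instructions","ease_of_use","Are the instructions on use clear and easy to follow?",4
"P3","ease_interface","ease_of_use","Is the user interface pleasant?",4
"P3","playability","playability","Is the exergame easy to be played?",4
"P3","enjoyment_trainer","enjoyment","Does a virtual trainer increase the enjoyment towards exercise?",4
"P3","satisfaction","satisfaction","Are you satisfied of the experience with the exergame?",3
"P3","acceptance_home","acceptance","Are you motivated to use the exergame autonomously at home?",3
"P4","ease_hw_instructions","ease_of_use","Are the instructions on the hardware configuration clear to follow?",4
"P4","ease_hw_setup","ease_of_use","Is the hardware configuration easy in practice?",4
"P4","ease_use_instructions","ease_of_use","Are the instructions on use clear and easy to follow?",4
"P4","ease_interface","ease_of_use","Is the user interface pleasant?",4
"P4","playability","playability","Is the exergame easy to be played?",4
"P4","enjoyment_trainer","enjoyment","Does a virtual trainer increase the enjoyment towards exercise?",4
"P4","satisfaction","satisfaction","Are you satisfied of the experience with the exergame?",4
"P4","acceptance_home","acceptance","Are you motivated to use the exergame autonomously at home?",5
"P5","ease_hw_instructions","ease_of_use","Are the instructions on the hardware configuration clear to follow?",4
"P5","ease_hw_setup","ease_of_use","Is the hardware configuration easy in practice?",4
"P5","ease_use_instructions","ease_of_use","Are the instructions on use clear and easy to follow?",5
"P5","ease_interface","ease_of_use","Is the user interface pleasant?",4
"P5","playability","playability","Is the exergame easy to be played?",4
"P5","enjoyment_trainer","enjoyment","Does a virtual trainer increase the enjoyment towards exercise?",5
"P5","satisfaction","satisfaction","Are you satisfied of the experience with the exergame?",5
"P5","acceptance_home","acceptance","Are you motivated to use the exergame autonomously at home?",5
"P6","ease_hw_instructions","ease_of_use","Are the instructions on the hardware configuration clear to follow?",4
"P6","ease_hw_setup","ease_of_use","Is the hardware configuration easy in practice?",4
"P6","ease_use_instructions","ease_of_use","Are the instructions on use clear and easy to follow?",4
"P6","ease_interface","ease_of_use","Is the user interface pleasant?",3
"P6","playability","playability","Is the exergame easy to be played?",4
"P6","enjoyment_trainer","enjoyment","Does a virtual trainer increase the enjoyment towards exercise?",3
"P6","satisfaction","satisfaction","Are you satisfied of the experience with the exergame?",4
"P6","acceptance_home","acceptance","Are you motivated to use the exergame autonomously at home?",5
"P7","ease_hw_instructions","ease_of_use","Are the instructions on the hardware configuration clear to follow?",4
"P7","ease_hw_setup","ease_of_use","Is the hardware configuration easy in practice?",4
"P7","ease_use_instructions","ease_of_use","Are the instructions on use clear and easy to follow?",4
"P7","ease_interface","ease_of_use","Is the user interface pleasant?",4
"P7","playability","playability","Is the exergame easy to be played?",4
"P7","enjoyment_trainer","enjoyment","Does a virtual trainer increase the enjoyment towards exercise?",4
"P7","satisfaction","satisfaction","Are you satisfied of the experience with the exergame?",4
"P7","acceptance_home","acceptance","Are you motivated to use the exergame autonomously at home?",5
"P8","ease_hw_instructions","ease_of_use","Are the instructions on the hardware configuration clear to follow?",4
"P8","ease_hw_setup","ease_of_use","Is the hardware configuration easy in practice?",4
"P8","ease_use_instructions","ease_of_use","Are the instructions on use clear and easy to follow?",4
"P8","ease_interface","ease_of_use","Is the user interface pleasant?",4
"P8","playability","playability","Is the exergame easy to be played?",4
"P8","enjoyment_trainer","enjoyment","Does a virtual trainer increase the enjoyment towards exercise?",4
"P8","satisfaction","satisfaction","Are you satisfied of the experience with the exergame?",4
"P8","acceptance_home","acceptance","Are you motivated to use the exergame autonomously at home?",5
"P9","ease_hw_instructions","ease_of_use","Are the instructions on the hardware configuration clear to follow?",4
"P9","ease_hw_setup","ease_of_use","Is the hardware configuration easy in practice?",2
"P9","ease_use_instructions","ease_of_use","Are the instructions on use clear and easy to follow?",4
"P9","ease_interface","ease_of_use","Is the user interface pleasant?",3
"P9","playability","playability","Is the exergame easy to be played?",2
"P9","enjoyment_trainer","enjoyment","Does a virtual trainer increase the enjoyment towards exercise?",5
"P9","satisfaction","satisfaction","Are you satisfied of the experience with the exergame?",4
"P9","acceptance_home","acceptance","Are you motivated to use the exergame autonomously at home?",5
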